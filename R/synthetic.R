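# run code with a temporary RNG state so generators are pure in (spec, seed)
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Specification of a synthetic vessel-network image
#'
#' Describes a random planar network and how it is rendered: nodes are
#' scattered on a jittered lattice over a square domain and linked to
#' lattice-adjacent neighbours with a connection probability, which keeps
#' tubes from crossing, so the drawn graph IS the topological ground truth.
#' Edges are rendered as tubes of the stated width, blurred and corrupted
#' with noise.
#'
#' @param n_seeds Number of candidate nodes (placed on a
#'   `ceiling(sqrt(n_seeds))`-square lattice).
#' @param domain_um Side of the square imaged domain (um).
#' @param tube_width_um Length-2 range (or single value) of tube widths (um).
#' @param connect_prob Probability each lattice-adjacent node pair is linked.
#' @param noise_sd Additive Gaussian noise s.d. on the 8-bit scale.
#' @param sp_prob Salt-and-pepper pixel corruption probability.
#' @param pixel_size Rendered pixel size (um).
#' @param seed RNG seed; identical spec + seed gives a bit-identical image.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_seeds = 25, domain_um = 1000,
                         tube_width_um = c(14, 22), connect_prob = 0.7,
                         noise_sd = 8, sp_prob = 0.001,
                         pixel_size = 4, seed = 1) {
  stopifnot(n_seeds >= 2, domain_um > 0, all(tube_width_um > 0),
            connect_prob >= 0, connect_prob <= 1, pixel_size > 0)
  if (length(tube_width_um) == 1L) tube_width_um <- rep(tube_width_um, 2)
  structure(list(n_seeds = n_seeds, domain_um = domain_um,
                 tube_width_um = sort(tube_width_um),
                 connect_prob = connect_prob, noise_sd = noise_sd,
                 sp_prob = sp_prob, pixel_size = pixel_size, seed = seed),
            class = "network_spec")
}

# render thick line segments into a logical raster [n x n]
render_tubes <- function(nodes_px, edges, widths_px, n) {
  mask <- matrix(FALSE, n, n)
  if (!nrow(edges)) return(mask)
  for (e in seq_len(nrow(edges))) {
    a <- nodes_px[edges[e, 1], ]; b <- nodes_px[edges[e, 2], ]
    r <- widths_px[e] / 2
    r0 <- max(1L, floor(min(a[1], b[1]) - r - 1))
    r1 <- min(n, ceiling(max(a[1], b[1]) + r + 1))
    c0 <- max(1L, floor(min(a[2], b[2]) - r - 1))
    c1 <- min(n, ceiling(max(a[2], b[2]) + r + 1))
    rows <- r0:r1; cols <- c0:c1
    py <- matrix(rows, length(rows), length(cols))
    px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    # distance from each pixel centre to the segment ab
    vx <- b[2] - a[2]; vy <- b[1] - a[1]
    len2 <- vx^2 + vy^2
    tt <- if (len2 > 0) pmin(1, pmax(0, ((px - a[2]) * vx + (py - a[1]) * vy) / len2))
          else 0
    dx <- px - (a[2] + tt * vx); dy <- py - (a[1] + tt * vy)
    hit <- (dx^2 + dy^2) <= r^2
    mask[rows, cols] <- mask[rows, cols] | hit
  }
  mask
}

# build the jittered-lattice graph for a network_spec (inside with_seed)
sample_network_graph <- function(spec) {
  m <- ceiling(sqrt(spec$n_seeds))
  cell <- spec$domain_um / (m + 1)
  ij <- expand.grid(i = seq_len(m), j = seq_len(m))[seq_len(spec$n_seeds), ]
  jit <- matrix(stats::runif(2 * nrow(ij), -0.22, 0.22), ncol = 2)
  nodes <- cbind(y = (ij$i + jit[, 1]) * cell,
                 x = (ij$j + jit[, 2]) * cell)   # um
  # lattice-adjacent candidate edges (right and down neighbours)
  cand <- NULL
  for (r in seq_len(nrow(ij))) {
    i <- ij$i[r]; j <- ij$j[r]
    for (d in list(c(0, 1), c(1, 0))) {
      s <- which(ij$i == i + d[1] & ij$j == j + d[2])
      if (length(s)) cand <- rbind(cand, c(r, s))
    }
  }
  keep <- stats::runif(nrow(cand)) < spec$connect_prob
  edges <- cand[keep, , drop = FALSE]
  widths <- stats::runif(nrow(edges), spec$tube_width_um[1],
                         spec$tube_width_um[2])
  list(nodes = nodes, edges = edges, widths = widths)
}

# topology + geometry ground truth of a node/edge graph (um coordinates)
graph_truth <- function(nodes, edges, widths = NULL) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = nrow(nodes))
  seg_len <- if (nrow(edges)) sqrt(rowSums(
    (nodes[edges[, 1], , drop = FALSE] -
     nodes[edges[, 2], , drop = FALSE])^2)) else numeric(0)
  list(n_endpoints = sum(deg == 1),
       n_junctions = sum(deg >= 3),
       total_length = sum(seg_len) / 1000,        # mm
       degrees = deg,
       edge_lengths_um = seg_len,
       widths_um = widths)
}

#' Generate a ground-truthed synthetic vessel-network image
#'
#' Draws the random planar network described by a [network_spec()], renders
#' its edges as bright tubes on a dark background (Gaussian blur, additive
#' Gaussian noise and salt-and-pepper corruption), and reports the ground
#' truth computed from the generating graph itself — never from the
#' rendered image: endpoint count (degree-1 nodes), junction count
#' (degree >= 3 nodes) and total geometric length.
#'
#' @param spec A [network_spec()].
#' @return List with `frame` (an [image_frame()]) and `truth` (list:
#'   `n_endpoints`, `n_junctions`, `total_length` in mm, `rendered_area`
#'   in mm^2, node `degrees`, plus the clean `mask`).
#' @export
generate_network_image <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  n <- round(spec$domain_um / spec$pixel_size)
  if (n < 8) stop("degenerate domain: image smaller than 8 px", call. = FALSE)
  with_seed(spec$seed, {
    g <- sample_network_graph(spec)
    truth <- graph_truth(g$nodes, g$edges, g$widths)
    mask <- render_tubes(g$nodes / spec$pixel_size, g$edges,
                         g$widths / spec$pixel_size, n)
    img <- matrix(30, n, n)
    img[mask] <- 200
    img <- EBImage::gblur(EBImage::Image(img / 255), sigma = 1)
    img <- matrix(as.numeric(EBImage::imageData(img)), n, n) * 255
    img <- img + stats::rnorm(n * n, 0, spec$noise_sd)
    sp <- stats::runif(n * n) < spec$sp_prob
    img[sp] <- ifelse(stats::runif(sum(sp)) < 0.5, 0, 255)
    img <- pmin(pmax(img, 0), 255)
    truth$rendered_area <- sum(mask) * spec$pixel_size^2 / 1e6  # mm^2
    truth$mask <- mask
    list(frame = image_frame(img, spec$pixel_size), truth = truth)
  })
}

#' Generate a ground-truthed synthetic lipid-droplet image
#'
#' Renders dark, non-overlapping circular droplets on a bright background
#' (emulating brightfield images of adipocytes) until the rendered dark
#' pixel fraction reaches the target coverage. The achieved pixel fraction
#' is recorded as ground truth.
#'
#' @param target_fraction Target coverage in percent, within `[0, 60]`
#'   (above ~60% non-overlapping discs cannot pack).
#' @param radius_range_um Length-2 range of droplet radii (um).
#' @param seed RNG seed.
#' @param domain_um Side of the square imaged domain (um).
#' @param pixel_size Pixel size (um).
#' @param noise_sd Additive Gaussian noise s.d. (8-bit scale).
#' @param max_attempts Placement attempts before declaring the target
#'   unreachable.
#' @return List with `frame` (an [image_frame()]) and `truth` (list:
#'   `fraction_pct` achieved, `n_droplets`, `centers`, `radii_um`, `mask`).
#' @export
generate_lipid_image <- function(target_fraction = 20,
                                 radius_range_um = c(8, 20), seed = 1,
                                 domain_um = 1000, pixel_size = 4,
                                 noise_sd = 6, max_attempts = 20000) {
  stopifnot(target_fraction >= 0, target_fraction <= 60,
            all(radius_range_um > 0), domain_um > 0, pixel_size > 0)
  n <- round(domain_um / pixel_size)
  with_seed(seed, {
    mask <- matrix(FALSE, n, n)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    npx <- n * n
    frac <- function() 100 * sum(mask) / npx
    attempts <- 0L
    while (frac() < target_fraction - 0.25 && attempts < max_attempts) {
      attempts <- attempts + 1L
      r <- stats::runif(1, radius_range_um[1], radius_range_um[2])
      # near the target, shrink the droplet to avoid overshooting
      deficit_px <- (target_fraction - frac()) / 100 * npx
      r <- min(r, max(radius_range_um[1],
                      pixel_size * sqrt(deficit_px / pi)))
      cy <- stats::runif(1, r, domain_um - r)
      cx <- stats::runif(1, r, domain_um - r)
      if (nrow(centers) && any(sqrt((centers[, 1] - cy)^2 +
                                    (centers[, 2] - cx)^2) <
                               radii + r + pixel_size)) next
      rows <- max(1, floor((cy - r) / pixel_size)):min(n, ceiling((cy + r) / pixel_size))
      cols <- max(1, floor((cx - r) / pixel_size)):min(n, ceiling((cx + r) / pixel_size))
      py <- (matrix(rows, length(rows), length(cols)) - 0.5) * pixel_size
      px <- (matrix(cols, length(rows), length(cols), byrow = TRUE) - 0.5) * pixel_size
      hit <- (py - cy)^2 + (px - cx)^2 <= r^2
      mask[rows, cols] <- mask[rows, cols] | hit
      centers <- rbind(centers, c(cy, cx))
      radii <- c(radii, r)
    }
    if (frac() < target_fraction - 1)
      stop(sprintf(
        "could not reach %.1f%% coverage with radii [%g, %g] um after %d attempts (achieved %.1f%%)",
        target_fraction, radius_range_um[1], radius_range_um[2],
        max_attempts, frac()), call. = FALSE)
    img <- matrix(220, n, n)
    img[mask] <- 45
    img <- img + stats::rnorm(npx, 0, noise_sd)
    img <- pmin(pmax(img, 0), 255)
    list(frame = image_frame(img, pixel_size),
         truth = list(fraction_pct = frac(), n_droplets = length(radii),
                      centers = centers, radii_um = radii, mask = mask))
  })
}

#' Generate a synthetic vasculogenesis time-lapse stack
#'
#' Emulates the three morphogenetic phases seen in vasculogenesis
#' time-lapses: network metrics rise sharply to a peak at the end of the
#' rise phase (early vessel formation), decline during remodelling, then
#' plateau. A master planar network is sampled once; each frame activates a
#' time-varying subset of its edges (growing through the rise phase,
#' receding in a fixed order afterwards) and is rendered like
#' [generate_network_image()]. Ground-truth junction/endpoint/length
#' trajectories are computed from each frame's active subgraph.
#'
#' @param rise_days,decline_days,plateau_days Phase durations (days), > 0.
#' @param frame_interval Time between frames (s).
#' @param seed RNG seed.
#' @param spec [network_spec()] for the master network (its `seed` is
#'   ignored in favour of `seed`).
#' @param plateau_level Fraction of edges active during the plateau.
#' @return List with `stack` (list of [image_frame()]s, timestamps set) and
#'   `truth` (data frame per frame: `time_s`, `n_active_edges`,
#'   `n_junctions`, `n_endpoints`, `total_length` in mm).
#' @export
generate_vasculogenesis_timelapse <- function(rise_days = 0.5,
                                              decline_days = 3.5,
                                              plateau_days = 3,
                                              frame_interval = 1800,
                                              seed = 1,
                                              spec = network_spec(n_seeds = 25,
                                                                  domain_um = 800,
                                                                  pixel_size = 5),
                                              plateau_level = 0.55) {
  stopifnot(rise_days > 0, decline_days > 0, plateau_days > 0,
            frame_interval > 0, plateau_level > 0, plateau_level < 1)
  total_s <- (rise_days + decline_days + plateau_days) * 86400
  times <- seq(0, total_s, by = frame_interval)
  n <- round(spec$domain_um / spec$pixel_size)
  with_seed(seed, {
    g <- sample_network_graph(spec)
    ne <- nrow(g$edges)
    order_add <- sample.int(ne)        # activation order
    # activity profile in [0, 1]
    v <- function(t) {
      td <- t / 86400
      ifelse(td <= rise_days, td / rise_days,
        ifelse(td <= rise_days + decline_days,
          1 - (1 - plateau_level) * (td - rise_days) / decline_days,
          plateau_level))
    }
    active_n <- pmax(1L, round(v(times) * ne))
    stack <- vector("list", length(times))
    truth <- vector("list", length(times))
    noise_seeds <- sample.int(.Machine$integer.max - 1L, length(times))
    for (f in seq_along(times)) {
      idx <- order_add[seq_len(active_n[f])]
      ed <- g$edges[idx, , drop = FALSE]
      tr <- graph_truth(g$nodes, ed)
      mask <- render_tubes(g$nodes / spec$pixel_size, ed,
                           g$widths[idx] / spec$pixel_size, n)
      img <- matrix(30, n, n)
      img[mask] <- 200
      img <- EBImage::gblur(EBImage::Image(img / 255), sigma = 1)
      img <- matrix(as.numeric(EBImage::imageData(img)), n, n) * 255
      img <- with_seed(noise_seeds[f],
                       img + stats::rnorm(n * n, 0, spec$noise_sd))
      img <- pmin(pmax(img, 0), 255)
      stack[[f]] <- image_frame(img, spec$pixel_size, timestamp = times[f])
      truth[[f]] <- data.frame(time_s = times[f], n_active_edges = length(idx),
                               n_junctions = tr$n_junctions,
                               n_endpoints = tr$n_endpoints,
                               total_length = tr$total_length)
    }
    list(stack = stack, truth = do.call(rbind, truth))
  })
}

#' Generate an analytic transport-solver test case
#'
#' Emits a simulator configuration together with the closed-form field the
#' simulation must reproduce:
#' \describe{
#'   \item{pure_decay}{No diffusion, channel segments disabled, uniform
#'     initial concentration: `C(t) = C0 * 2^(-t / t_half)` everywhere.}
#'   \item{steady_uniform}{Negligible decay (very long half-life), top and
#'     bottom edges fully clamped at `C0`: the long-time field is uniformly
#'     `C0`.}
#'   \item{reflection_symmetry}{The same factor loaded from the left in one
#'     configuration and from the right in its mirror: the two fields must
#'     be mirror images.}
#' }
#'
#' @param kind One of `"pure_decay"`, `"steady_uniform"`,
#'   `"reflection_symmetry"`.
#' @param c0 Concentration scale (ng/mL).
#' @return List with the configuration (`factor`, `geometry`, `grid`,
#'   `schedule`, extra `sim_args`) and `expected`, a function of the
#'   snapshot times returning the expected cell value(s).
#' @export
generate_pde_testcase <- function(kind = c("pure_decay", "steady_uniform",
                                           "reflection_symmetry"),
                                  c0 = 10) {
  kind <- match.arg(kind)
  geom <- chip_geometry(length = 2, width = 1, channel_segment_length = 1,
                        channel_style = "edge")
  grid <- sim_grid(geom, spacing = 0.1)
  gf <- growth_factor("probe", c0, 1000, 100, 3600, c0 / 4)
  fs <- list(probe = gf)
  full <- media_composition("probe_media", c(probe = c0), fs)
  blank <- media_composition("blank", stats::setNames(numeric(0), character(0)), fs)
  switch(kind,
    pure_decay = {
      gf$diffusivity <- 0     # pure decay: transport switched off
      list(kind = kind, factor = gf, geometry = geom, grid = grid,
           schedule = single_loading_schedule(full, blank, 0.25),
           sim_args = list(disable_segments = TRUE,
                           initial = matrix(c0, grid$ny, grid$nx)),
           expected = function(t) c0 * 2^(-t / gf$half_life))
    },
    steady_uniform = {
      gf$half_life <- 1e12    # effectively no decay over the test horizon
      list(kind = kind, factor = gf, geometry = geom, grid = grid,
           schedule = single_loading_schedule(full, full, 2),
           sim_args = list(),
           expected = function(t) rep(c0, length(t)))
    },
    reflection_symmetry = {
      list(kind = kind, factor = gf, geometry = geom, grid = grid,
           schedule_left = single_loading_schedule(full, blank, 0.25),
           schedule_right = single_loading_schedule(blank, full, 0.25),
           sim_args = list(),
           expected = function(field) field$values[, rev(seq_len(grid$nx)), ,
                                                   drop = FALSE])
    })
}

#' Write a synthetic image (or stack) with its ground-truth sidecar
#'
#' Writes frames as TIFF (grayscale, 8-bit scale mapped to `[0, 1]`) and the
#' ground truth as a JSON sidecar next to them.
#'
#' @param x Result of [generate_network_image()], [generate_lipid_image()]
#'   or [generate_vasculogenesis_timelapse()].
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Invisible character vector of paths written.
#' @export
write_synthetic_dataset <- function(x, dir, name = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  frames <- if (!is.null(x$stack)) x$stack else list(x$frame)
  for (i in seq_along(frames)) {
    p <- file.path(dir, if (length(frames) > 1)
      sprintf("%s_%04d.tif", name, i) else paste0(name, ".tif"))
    tiff::writeTIFF(frames[[i]]$pixels / 255, p, bits.per.sample = 8L)
    paths <- c(paths, p)
  }
  truth <- x$truth
  truth$mask <- NULL    # raster truth lives in the image, not the sidecar
  jp <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(truth, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(c(paths, jp))
}
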