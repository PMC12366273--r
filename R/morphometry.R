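#' Construct an image frame for analysis
#'
#' Wraps a 2D pixel array with its physical pixel size. Colour (RGB) input
#' is converted to 8-bit grayscale via the Rec. 601 luminance weights before
#' any analysis, and grayscale input on a `[0, 1]` scale is rescaled to
#' 8-bit (0-255).
#'
#' @param pixels Numeric matrix (grayscale) or `h x w x 3` array (RGB).
#'   Values either in `[0, 1]` or already on a 0-255 (8-bit) scale.
#' @param pixel_size Physical size of one pixel (um), > 0.
#' @param timestamp Optional acquisition time (s).
#' @return An object of class `image_frame` with `pixels` on the 0-255
#'   scale, `pixel_size` and `timestamp`.
#' @export
image_frame <- function(pixels, pixel_size, timestamp = NULL) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] < 3L)
      stop("colour images must have 3 channels", call. = FALSE)
    pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] +
      0.114 * pixels[, , 3]
  }
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  if (max(pixels) <= 1) pixels <- pixels * 255
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 timestamp = timestamp),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px at %g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              if (!is.null(x$timestamp))
                sprintf(", t = %g s", x$timestamp) else ""))
  invisible(x)
}

#' Read a TIFF or PNG image as an image frame
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size Physical pixel size (um).
#' @param timestamp Optional acquisition time (s).
#' @return An [image_frame()].
#' @export
read_image_frame <- function(path, pixel_size, timestamp = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (is.array(px) && length(dim(px)) == 3L && dim(px)[3] == 4L)
    px <- px[, , 1:3]  # drop alpha
  image_frame(px, pixel_size, timestamp)
}

# -- binary mask helpers ------------------------------------------------

# 8-connected labelling via EBImage; returns integer matrix of labels
label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
}

# remove connected components smaller than min_px pixels
remove_small <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label8(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_px)
  mask & (lab %in% keep) & matrix(TRUE, nrow(mask), ncol(mask))
}

# fill enclosed background regions smaller than max_px pixels
fill_small_holes <- function(mask, max_px) {
  if (max_px < 1 || all(mask)) return(mask)
  lab <- label8(!mask)
  if (!max(lab)) return(mask)
  sizes <- tabulate(lab)
  # background components touching the border are not holes
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  holes <- setdiff(which(sizes <= max_px), border)
  if (length(holes)) mask[lab %in% holes] <- TRUE
  mask
}

#' Segment vessels from a fluorescence image
#'
#' Thresholds the image at a user-defined intensity (default: Otsu's
#' threshold), removes small bright particles (single cells, debris) below
#' `min_particle_area`, and fills enclosed dark holes within vessels up to
#' `max_hole_area`.
#'
#' @param frame An [image_frame()].
#' @param intensity_threshold Threshold on the 8-bit intensity scale
#'   (`[0, 255]`); pixels `>=` threshold are vessel. `NULL` (default) uses
#'   Otsu's method.
#' @param min_particle_area Minimum connected-component area kept (um^2).
#' @param max_hole_area Maximum enclosed hole area filled (um^2).
#' @return Logical matrix (vessel mask) with attribute `threshold`.
#' @export
binarize_vessels <- function(frame, intensity_threshold = NULL,
                             min_particle_area = 500, max_hole_area = 100) {
  stopifnot(inherits(frame, "image_frame"))
  px <- frame$pixels
  if (is.null(intensity_threshold)) {
    intensity_threshold <- EBImage::otsu(EBImage::Image(px / 255),
                                         range = c(0, 1)) * 255
  } else if (intensity_threshold < 0 || intensity_threshold > 255) {
    stop("intensity_threshold outside the 8-bit dynamic range [0, 255]",
         call. = FALSE)
  }
  mask <- px >= intensity_threshold
  a <- frame$pixel_size^2
  mask <- remove_small(mask, ceiling(min_particle_area / a))
  mask <- fill_small_holes(mask, floor(max_hole_area / a))
  attr(mask, "threshold") <- intensity_threshold
  mask
}

# -- skeletonisation ----------------------------------------------------

# shift a logical/numeric matrix by (dr, dc), padding with 0/FALSE
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(if (is.logical(m)) FALSE else 0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Reduce a binary mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen morphological thinning: pixels are iteratively removed from
#' the mask boundary, alternating two deletion templates, until no further
#' pixel can be deleted without breaking connectivity. The result preserves
#' the mask's topology and is the basis of the vessel-network metrics.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask & TRUE
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # clockwise 8-neighbourhood P2..P9 starting north
      P2 <- shift_mat(m, -1,  0); P3 <- shift_mat(m, -1,  1)
      P4 <- shift_mat(m,  0,  1); P5 <- shift_mat(m,  1,  1)
      P6 <- shift_mat(m,  1,  0); P7 <- shift_mat(m,  1, -1)
      P8 <- shift_mat(m,  0, -1); P9 <- shift_mat(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      if (step == 1) {
        cond <- !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  clean_corners(m)
}

# remove redundant corner pixels the thinning leaves behind: a pixel with
# exactly two, mutually adjacent, neighbours can be deleted without
# breaking connectivity. Terminal corners otherwise mask true endpoints
# (the terminus reads 2 neighbours instead of 1). Sequential deletion with
# local recheck so adjacent candidates cannot eat each other.
clean_corners <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    nb <- neighbor_count(m)
    cand <- which(m & nb == 2 & crossing_number(m) == 1)
    removed <- FALSE
    for (p in cand) {
      r <- (p - 1L) %% nr + 1L; cl <- (p - 1L) %/% nr + 1L
      rs <- max(1, r - 1):min(nr, r + 1)
      cs <- max(1, cl - 1):min(nc, cl + 1)
      w <- m[rs, cs]
      w[rs == r, cs == cl] <- FALSE
      nbr <- which(w, arr.ind = TRUE)
      if (nrow(nbr) != 2L) next                     # stale after a deletion
      if (max(abs(nbr[1, ] - nbr[2, ])) == 1L) {    # mutually adjacent
        m[r, cl] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# 8-neighbour count of each skeleton pixel
neighbor_count <- function(skel) {
  shift_mat(skel, -1, 0) + shift_mat(skel, 1, 0) +
  shift_mat(skel, 0, -1) + shift_mat(skel, 0, 1) +
  shift_mat(skel, -1, -1) + shift_mat(skel, -1, 1) +
  shift_mat(skel, 1, -1) + shift_mat(skel, 1, 1)
}

# crossing number: 0->1 transitions around the 8-neighbourhood. A skeleton
# pixel with crossing number >= 3 is a true branch point; staircase corner
# pixels have 3 raw neighbours but crossing number 2 and are not branches.
crossing_number <- function(skel) {
  P2 <- shift_mat(skel, -1,  0); P3 <- shift_mat(skel, -1,  1)
  P4 <- shift_mat(skel,  0,  1); P5 <- shift_mat(skel,  1,  1)
  P6 <- shift_mat(skel,  1,  0); P7 <- shift_mat(skel,  1, -1)
  P8 <- shift_mat(skel,  0, -1); P9 <- shift_mat(skel, -1, -1)
  (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
  (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
}

# skeleton path length in pixels: orthogonal steps 1, diagonal sqrt(2);
# diagonal links that shortcut an existing orthogonal corner are dropped
# so staircase corners are not double counted
skeleton_length_px <- function(skel) {
  E  <- skel & shift_mat(skel, 0, -1)   # link to east neighbour
  S  <- skel & shift_mat(skel, -1, 0)   # link to south neighbour
  SE <- skel & shift_mat(skel, -1, -1)
  NE <- skel & shift_mat(skel, 1, -1)
  # diagonal (i,j)-(i+1,j+1) is redundant if (i+1,j) or (i,j+1) is set
  SEr <- SE & !(shift_mat(skel, -1, 0) | shift_mat(skel, 0, -1))
  NEr <- NE & !(shift_mat(skel, 1, 0) | shift_mat(skel, 0, -1))
  sum(E) + sum(S) + sqrt(2) * (sum(SEr) + sum(NEr))
}

# prune terminal skeleton branches shorter than min_px (path length).
# Iterative: endpoint pixels whose removal eats a short branch are deleted.
prune_spurs <- function(skel, min_px) {
  if (min_px <= 0) return(skel)
  for (i in seq_len(ceiling(min_px))) {
    nb <- neighbor_count(skel)
    ends <- skel & nb == 1
    if (!any(ends)) break
    # stop eating a branch when the next pixel is a true branch point:
    # deleting an endpoint adjacent to one would shorten a real vessel
    branch <- skel & crossing_number(skel) >= 3
    keep <- ends & (shift_mat(branch, -1, 0) | shift_mat(branch, 1, 0) |
                    shift_mat(branch, 0, -1) | shift_mat(branch, 0, 1) |
                    shift_mat(branch, -1, -1) | shift_mat(branch, -1, 1) |
                    shift_mat(branch, 1, -1) | shift_mat(branch, 1, 1))
    del <- ends & !keep
    if (!any(del)) break
    skel[del] <- FALSE
  }
  clean_corners(skel)
}

# dilate a logical mask with a disc of radius r (pixels)
dilate_disc <- function(mask, r) {
  if (r < 1 || !any(mask)) return(mask)
  kern <- EBImage::makeBrush(2 * floor(r) + 1, shape = "disc")
  out <- EBImage::dilate(EBImage::Image(mask * 1), kern)
  matrix(as.numeric(EBImage::imageData(out)) > 0.5, nrow(mask), ncol(mask))
}

#' Vessel-network morphology metrics from a binary mask
#'
#' Skeletonises the mask and measures the network's topology and size:
#' endpoints are skeleton pixels with exactly one neighbour; junctions are
#' 8-connected clusters of skeleton pixels with three or more neighbours
#' (one thick crossing counts once); total length is the skeleton path
#' length (diagonal steps weighted sqrt(2), staircase corners not double
#' counted) scaled by pixel size; total area is the mask area.
#'
#' Skeletonising a thick tube leaves short artefactual side branches at
#' rounded caps and bends; terminal branches shorter than `prune_length`
#' are removed first. The default prunes branches shorter than the mask's
#' typical vessel radius (from the distance transform), the length scale of
#' such artefacts.
#'
#' @param mask Logical matrix (vessel mask), e.g. from [binarize_vessels()].
#' @param pixel_size Pixel size (um).
#' @param prune_length Terminal branches shorter than this (um) are removed
#'   before measuring; `NULL` (default) uses the typical vessel radius.
#' @return An object of class `vessel_metrics`: list with `n_junctions`,
#'   `n_endpoints`, `total_length` (mm), `total_area` (mm^2).
#' @export
vessel_metrics <- function(mask, pixel_size, prune_length = NULL) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  mask <- mask & TRUE
  empty <- structure(list(n_junctions = 0L, n_endpoints = 0L,
                          total_length = 0, total_area = 0),
                     class = "vessel_metrics")
  if (!any(mask)) return(empty)
  skel <- skeletonize(mask)
  radius_px <- stats::median(mask_radius_px(mask, skel))
  prune_px <- if (is.null(prune_length)) radius_px
              else prune_length / pixel_size
  skel <- prune_spurs(skel, prune_px)
  if (!any(skel)) return(within_metrics(empty, mask, pixel_size))
  nb <- neighbor_count(skel)
  n_end <- sum(skel & nb == 1)
  branch <- skel & crossing_number(skel) >= 3
  # cluster branch pixels within one vessel radius: a thick crossing whose
  # thinning splits into nearby T-branches still counts as one junction
  n_junc <- if (any(branch)) max(label8(dilate_disc(branch, radius_px))) else 0L
  structure(list(
    n_junctions = as.integer(n_junc),
    n_endpoints = as.integer(n_end),
    total_length = skeleton_length_px(skel) * pixel_size / 1000,
    total_area = sum(mask) * pixel_size^2 / 1e6),
    class = "vessel_metrics")
}

# distance-transform radii (px) at skeleton pixels (vessel half-widths)
mask_radius_px <- function(mask, skel = NULL) {
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dm <- matrix(as.numeric(EBImage::imageData(dm)), nrow(mask), ncol(mask))
  if (is.null(skel) || !any(skel)) dm[mask] else dm[skel]
}

within_metrics <- function(m, mask, pixel_size) {
  m$total_area <- sum(mask) * pixel_size^2 / 1e6
  m
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf(
    "<vessel_metrics> %d junctions, %d endpoints, length %.3f mm, area %.4f mm^2%s\n",
    x$n_junctions, x$n_endpoints, x$total_length, x$total_area,
    if (!is.null(x$mean_diameter))
      sprintf(", diameter %.1f um", x$mean_diameter) else ""))
  invisible(x)
}

#' Estimate vessel diameter from a mask
#'
#' Automated surrogate for calliper measurements between junctions: the
#' mask is skeletonised, skeleton pixels near junctions are excluded, and
#' at up to `sample_points` remaining mid-segment pixels the local diameter
#' is read from the Euclidean distance transform as `2 d - 1` pixels (the
#' centreline of a tube `w` pixels wide sits `(w + 1)/2` pixels from
#' background).
#'
#' @param mask Logical vessel mask (must contain at least one vessel pixel).
#' @param pixel_size Pixel size (um).
#' @param sample_points Maximum number of skeleton pixels sampled.
#' @return List with `mean`, `sd` (um) and `n` (points sampled).
#' @export
vessel_diameter <- function(mask, pixel_size, sample_points = 200) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  if (!any(mask)) stop("empty mask: no vessels to measure", call. = FALSE)
  skel <- skeletonize(mask)
  radii <- mask_radius_px(mask, skel)
  skel <- prune_spurs(skel, stats::median(radii))
  if (!any(skel)) stop("no skeleton segment to sample", call. = FALSE)
  branch <- skel & crossing_number(skel) >= 3
  keep <- skel & !dilate_disc(branch, max(2, stats::median(radii)))
  if (!any(keep)) keep <- skel
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  dm <- matrix(as.numeric(EBImage::imageData(dm)), nrow(mask), ncol(mask))
  d <- dm[keep]
  if (length(d) > sample_points)
    d <- d[round(seq(1, length(d), length.out = sample_points))]
  diam <- (2 * d - 1) * pixel_size
  list(mean = mean(diam), sd = if (length(diam) > 1) stats::sd(diam) else 0,
       n = length(diam))
}

#' Vessel metrics along a time-lapse stack
#'
#' Analyses every `subsample`-th frame of an ordered stack. With the default
#' `endpoint_mode = "complete"` only frames that begin a complete group of
#' `subsample` frames are analysed (`floor(n_frames / subsample)` frames:
#' a 478-frame stack at every tenth yields 47); `"all"` analyses frame 0 and
#' every `subsample`-th thereafter regardless of the trailing partial group
#' (48 for the same stack).
#'
#' @param stack List of [image_frame()] objects, in time order.
#' @param subsample Analyse every n-th frame (n >= 1).
#' @param endpoint_mode `"complete"` or `"all"` (see above).
#' @param intensity_threshold,min_particle_area,max_hole_area Passed to
#'   [binarize_vessels()].
#' @param prune_length Passed to [vessel_metrics()].
#' @return Data frame with one row per analysed frame: `frame` (1-based
#'   index in the stack), `timestamp`, `n_junctions`, `n_endpoints`,
#'   `total_length`, `total_area`.
#' @export
timeseries_metrics <- function(stack, subsample = 1,
                               endpoint_mode = c("complete", "all"),
                               intensity_threshold = NULL,
                               min_particle_area = 500, max_hole_area = 100,
                               prune_length = NULL) {
  endpoint_mode <- match.arg(endpoint_mode)
  stopifnot(is.list(stack), subsample >= 1)
  if (!length(stack)) stop("empty stack", call. = FALSE)
  n <- length(stack)
  n_groups <- if (endpoint_mode == "complete") n %/% subsample
              else (n - 1) %/% subsample + 1
  if (n_groups < 1) n_groups <- 1
  idx <- (seq_len(n_groups) - 1L) * subsample + 1L
  rows <- lapply(idx, function(i) {
    fr <- stack[[i]]
    mask <- binarize_vessels(fr, intensity_threshold, min_particle_area,
                             max_hole_area)
    m <- vessel_metrics(mask, fr$pixel_size, prune_length)
    data.frame(frame = i,
               timestamp = if (is.null(fr$timestamp)) NA_real_ else fr$timestamp,
               n_junctions = m$n_junctions, n_endpoints = m$n_endpoints,
               total_length = m$total_length, total_area = m$total_area)
  })
  do.call(rbind, rows)
}

#' Lipid coverage of an image region
#'
#' Measures the percentage of a region of interest occupied by dark,
#' lipid-droplet-like pixels: pixels whose 8-bit intensity falls inside a
#' two-sided threshold band (default `[0, otsu]`, i.e. darker than Otsu's
#' split). The same measurement is repeated on each length-third of the
#' region (labelled vasculogenesis / middle / adipogenesis along the chip
#' length) and on consecutive bins of `bin_width` um along the length (the
#' last bin may be partial).
#'
#' @param frame An [image_frame()] (brightfield; droplets dark).
#' @param threshold_band Length-2 numeric, intensity band `[lo, hi]` on the
#'   0-255 scale counted as lipid; `NULL` uses `[0, otsu]`.
#' @param roi Region of interest as `c(row0, row1, col0, col1)` (1-based,
#'   inclusive) in pixels, or `NULL` for the whole frame.
#' @param bin_width Bin width along the length (um).
#' @param vasculogenesis_side `"left"` or `"right"`: which end of the
#'   image's x-axis (columns) is the vasculogenesis side for the per-third
#'   labels.
#' @return An object of class `lipid_coverage_profile`: list with `whole`
#'   (%), `thirds` (named length-3 vector, %), and `bins` (data frame with
#'   `start_um`, `end_um`, `coverage_pct`).
#' @export
lipid_coverage <- function(frame, threshold_band = NULL, roi = NULL,
                           bin_width = 370,
                           vasculogenesis_side = c("left", "right")) {
  vasculogenesis_side <- match.arg(vasculogenesis_side)
  stopifnot(inherits(frame, "image_frame"))
  px <- frame$pixels
  if (is.null(roi)) roi <- c(1L, nrow(px), 1L, ncol(px))
  stopifnot(length(roi) == 4L)
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(px) || roi[4] > ncol(px) ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("roi outside image bounds", call. = FALSE)
  sub <- px[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (is.null(threshold_band)) {
    th <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1)) * 255
    threshold_band <- c(0, th)
  }
  stopifnot(length(threshold_band) == 2L,
            threshold_band[1] <= threshold_band[2])
  lipid <- sub >= threshold_band[1] & sub <= threshold_band[2]
  if (vasculogenesis_side == "right")
    lipid <- lipid[, rev(seq_len(ncol(lipid))), drop = FALSE]
  nc <- ncol(lipid)
  cuts <- round(nc * c(1, 2) / 3)
  thirds <- c(
    vasculogenesis = 100 * mean(lipid[, seq_len(cuts[1]), drop = FALSE]),
    middle = 100 * mean(lipid[, (cuts[1] + 1):cuts[2], drop = FALSE]),
    adipogenesis = 100 * mean(lipid[, (cuts[2] + 1):nc, drop = FALSE]))
  bin_px <- max(1L, round(bin_width / frame$pixel_size))
  starts <- seq(1L, nc, by = bin_px)
  bins <- data.frame(
    start_um = (starts - 1L) * frame$pixel_size,
    end_um = pmin(starts + bin_px - 1L, nc) * frame$pixel_size,
    coverage_pct = vapply(starts, function(s)
      100 * mean(lipid[, s:min(s + bin_px - 1L, nc), drop = FALSE]),
      numeric(1)))
  structure(list(whole = 100 * mean(lipid), thirds = thirds, bins = bins,
                 threshold_band = threshold_band),
            class = "lipid_coverage_profile")
}

#' @export
print.lipid_coverage_profile <- function(x, ...) {
  cat(sprintf(
    "<lipid_coverage_profile> whole %.1f%%; thirds V/M/A %.1f/%.1f/%.1f%%; %d bins\n",
    x$whole, x$thirds[1], x$thirds[2], x$thirds[3], nrow(x$bins)))
  invisible(x)
}
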