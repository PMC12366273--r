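#' Simulate one growth factor's diffusion and decay over the compartment
#'
#' Integrates the transport model
#' \deqn{\partial C/\partial t = D (\partial^2 C/\partial x^2 +
#'   \partial^2 C/\partial y^2) + k C}
#' over the 2D culture compartment with an explicit forward-time
#' central-space (FTCS) scheme. `k = ln(0.5)/t_half` is the factor's
#' (negative) half-life decay rate. Chip walls are no-flux (mirrored ghost
#' cells); the cells under each channel-overlap region are clamped every
#' step to that reservoir's concentration of the factor, which itself
#' decays by half-life between media events. Channels whose reservoir never
#' carries the factor are treated as walls (the media there neither
#' supplies nor actively removes the factor). The interior starts at zero
#' concentration: fresh hydrogel contains no supplement.
#'
#' The time step is chosen automatically as `0.9 * spacing^2 / (4 D)`
#' (rounded down so a whole number of steps fits each snapshot interval),
#' which satisfies the FTCS stability condition `dt <= spacing^2/(4D)`.
#'
#' @param factor A [growth_factor()].
#' @param geometry A [chip_geometry()].
#' @param schedule A [feeding_schedule()] supplying boundary media over time.
#' @param grid A [sim_grid()]; defaults to 0.05 mm spacing on `geometry`.
#' @param duration Simulated time (s); defaults to the schedule duration.
#' @param snapshot_interval Time between stored snapshots (s); default 0.5 h.
#' @param factor_set Named list of [growth_factor()] records (half-lives for
#'   boundary decay); defaults to a set containing just `factor`.
#' @param disable_segments If `TRUE` all channel segments are treated as
#'   walls (no Dirichlet cells); used for closed-compartment test cases.
#' @param initial Optional `ny x nx` matrix of initial concentrations
#'   (ng/mL); default all zero.
#' @return A `concentration_field`: list with `factor`, `grid`, `geometry`,
#'   `times` (s, starting at 0) and `values`, an `ny x nx x n_times` array
#'   (row 1 = bottom edge, column 1 = left end).
#' @examples
#' gf <- growth_factor("IGF-1", 15, 7600, 159, 1440, 5)
#' geom <- chip_geometry()
#' med <- media_composition("vasc", c("IGF-1" = 15), list("IGF-1" = gf))
#' none <- media_composition("blank", stats::setNames(numeric(0), character(0)),
#'                           list("IGF-1" = gf))
#' sched <- single_loading_schedule(med, none, duration_days = 0.05)
#' fld <- simulate_factor(gf, geom, sched, sim_grid(geom, 0.1),
#'                        snapshot_interval = 1800)
#' @export
simulate_factor <- function(factor, geometry, schedule,
                            grid = sim_grid(geometry),
                            duration = schedule$duration,
                            snapshot_interval = 1800,
                            factor_set = NULL,
                            disable_segments = FALSE,
                            initial = NULL) {
  stopifnot(inherits(factor, "growth_factor"),
            inherits(geometry, "chip_geometry"),
            inherits(schedule, "feeding_schedule"),
            inherits(grid, "sim_grid"))
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (snapshot_interval <= 0 || snapshot_interval > duration)
    stop("snapshot_interval must be in (0, duration]", call. = FALSE)
  if (grid$ny < 2L)
    stop("grid too coarse: fewer than 2 cells across the width", call. = FALSE)
  if (is.null(factor_set)) factor_set <- stats::setNames(list(factor), factor$name)
  if (!factor$name %in% names(factor_set))
    factor_set[[factor$name]] <- factor

  h <- grid$spacing * 1000            # um
  D <- factor$diffusivity             # um^2/s
  k <- decay_rate(factor$half_life)   # 1/s
  ny <- grid$ny; nx <- grid$nx

  # dt: FTCS stability bound, fitted to snapshots (D = 0 is pure decay,
  # integrated exactly below, so any dt works)
  dt_max <- if (D > 0) 0.9 * h^2 / (4 * D) else snapshot_interval
  nsub <- max(1L, as.integer(ceiling(snapshot_interval / dt_max)))
  dt <- snapshot_interval / nsub

  snaps <- seq(0, duration, by = snapshot_interval)
  values <- array(0, dim = c(ny, nx, length(snaps)))

  C <- if (is.null(initial)) matrix(0, ny, nx) else {
    stopifnot(is.matrix(initial), nrow(initial) == ny, ncol(initial) == nx)
    initial
  }

  segs <- if (disable_segments) list() else segment_cells(geometry, grid)
  bc <- reservoir_timeline(schedule, factor$name, factor_set)
  # channel segments whose reservoir never carries the factor are treated
  # as walls, not zero-concentration sinks: the media there neither supplies
  # nor actively removes the factor from the hydrogel interface
  ev_times <- vapply(schedule$events, `[[`, numeric(1), "time")
  segs <- Filter(function(sg)
    any(bc(sg$reservoir, unique(c(0, ev_times))) > 0), segs)
  clamp <- function(C, t) {
    for (sg in segs) C[sg$rows, sg$cols] <- bc(sg$reservoir, t)
    C
  }

  # mirrored-ghost index maps for the five-point Laplacian
  iN <- c(2:ny, ny); iS <- c(1L, seq_len(ny - 1L))
  jE <- c(2:nx, nx); jW <- c(1L, seq_len(nx - 1L))
  alpha <- dt * D / h^2
  decay <- exp(dt * k)              # exact first-order decay per step

  C <- clamp(C, 0)
  values[, , 1L] <- C
  t <- 0
  for (s in seq_along(snaps)[-1L]) {
    for (i in seq_len(nsub)) {
      lap <- C[iN, ] + C[iS, ] + C[, jE] + C[, jW] - 4 * C
      C <- C * decay + alpha * lap
      t <- t + dt
      C <- clamp(C, t)
    }
    t <- snaps[s]                   # avoid drift from repeated addition
    C <- clamp(C, t)
    values[, , s] <- C
  }

  structure(list(factor = factor$name, grid = grid, geometry = geometry,
                 times = snaps, values = values),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf(
    "<concentration_field> %s: %d x %d cells, %d snapshots over %.2f days, max %.3g ng/mL\n",
    x$factor, x$grid$ny, x$grid$nx, length(x$times),
    max(x$times) / 86400, max(x$values)))
  invisible(x)
}

#' Simulate all factors supplied by a pair of media
#'
#' Runs [simulate_factor()] for every distinct growth factor named in either
#' media composition of a counter-current pair. Because the transport model
#' is linear, each factor's field is independent of the others and they are
#' integrated separately.
#'
#' @param media_pair Named list of two [media_composition()] objects,
#'   names giving the reservoir sides, e.g.
#'   `list(left = vascular, right = adipogenic)`.
#' @param geometry A [chip_geometry()].
#' @param schedule A [feeding_schedule()]; if `NULL`, a single loading of
#'   the pair at t = 0 over `duration` is used.
#' @param grid A [sim_grid()].
#' @param duration Simulated time (s).
#' @param snapshot_interval Snapshot spacing (s).
#' @param factor_set Named list of [growth_factor()] records.
#' @return A `simulation_result`: list with `fields` (named list of
#'   `concentration_field`), `media_pair`, `schedule`, `geometry`, `grid`.
#' @export
simulate_media <- function(media_pair, geometry = chip_geometry(),
                           schedule = NULL, grid = sim_grid(geometry),
                           duration = 2 * 86400, snapshot_interval = 1800,
                           factor_set = default_growth_factors()) {
  stopifnot(is.list(media_pair), length(media_pair) == 2L,
            all(vapply(media_pair, inherits, logical(1), "media_composition")),
            !is.null(names(media_pair)),
            all(names(media_pair) %in% c("left", "right")))
  factors <- unique(unlist(lapply(media_pair, function(m) names(m$factors))))
  if (!length(factors))
    stop("media pair supplies no growth factors", call. = FALSE)
  missing <- setdiff(factors, names(factor_set))
  if (length(missing))
    stop("no growth factor record for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(schedule))
    schedule <- feeding_schedule(
      lapply(names(media_pair), function(side)
        media_event(0, side, "full", media_pair[[side]])),
      duration)
  fields <- lapply(factors, function(f)
    simulate_factor(factor_set[[f]], geometry, schedule, grid,
                    duration, snapshot_interval, factor_set))
  names(fields) <- factors
  structure(list(fields = fields, media_pair = media_pair,
                 schedule = schedule, geometry = geometry, grid = grid),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d factor fields: %s\n",
              length(x$fields), paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Export a concentration field as long-format CSV
#'
#' Writes one row per (snapshot, cell): `time_h, x_mm, y_mm, factor,
#' concentration`.
#'
#' @param field A `concentration_field`.
#' @param path Output CSV path.
#' @param times_h Optional subset of snapshot times (hours) to export;
#'   default all.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path, times_h = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  keep <- seq_along(field$times)
  if (!is.null(times_h))
    keep <- which(field$times / 3600 %in% times_h)
  grid <- field$grid
  rows <- do.call(rbind, lapply(keep, function(s)
    data.frame(time_h = field$times[s] / 3600,
               x_mm = rep(grid$x, each = grid$ny),
               y_mm = rep(grid$y, times = grid$nx),
               factor = field$factor,
               concentration = as.vector(field$values[, , s]))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Plot a concentration-field snapshot as a heatmap PNG
#'
#' @param field A `concentration_field`.
#' @param time_h Snapshot time to plot, in hours (nearest snapshot used).
#' @param path Output PNG path.
#' @param ec50 Optional EC50 (ng/mL); if given, the bioactive contour is
#'   overlaid.
#' @return `path`, invisibly.
#' @export
plot_field_heatmap <- function(field, time_h, path, ec50 = NULL) {
  stopifnot(inherits(field, "concentration_field"))
  s <- which.min(abs(field$times / 3600 - time_h))
  z <- t(field$values[, , s])        # x along rows for image()
  grDevices::png(path, width = 900, height = 260)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::image(field$grid$x, field$grid$y, z,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE,
                  main = sprintf("%s at %.1f h (max %.3g ng/mL)",
                                 field$factor, field$times[s] / 3600, max(z)))
  if (!is.null(ec50) && max(z) >= ec50 && min(z) <= ec50)
    graphics::contour(field$grid$x, field$grid$y, z, levels = ec50,
                      add = TRUE, col = "white", lwd = 2, drawlabels = FALSE)
  invisible(path)
}
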