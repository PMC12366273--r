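#' Fraction of the culture area at bioactive concentration
#'
#' For each stored snapshot, the fraction of grid cells whose concentration
#' is at or above the factor's EC50 — the area predicted to receive a
#' bioactive dose.
#'
#' @param field A `concentration_field` from [simulate_factor()].
#' @param ec50 Bioactivity threshold (ng/mL), > 0.
#' @return Numeric vector, one fraction in `[0, 1]` per snapshot, named by
#'   snapshot time in hours.
#' @export
bioactive_fraction <- function(field, ec50) {
  stopifnot(inherits(field, "concentration_field"), ec50 > 0)
  n <- field$grid$nx * field$grid$ny
  frac <- apply(field$values >= ec50, 3, sum) / n
  stats::setNames(frac, sprintf("%.2f", field$times / 3600))
}

#' Bioactive distribution distance of a single snapshot
#'
#' The furthest distance from the fed end, measured along the compartment
#' length, at which any cell across the width is at or above the EC50. The
#' distance is taken to the far edge of the furthest bioactive cell, so full
#' coverage reads as the full compartment length. Returns 0 if no cell is
#' bioactive.
#'
#' @param snapshot `ny x nx` concentration matrix (column 1 = left end).
#' @param ec50 Bioactivity threshold (ng/mL).
#' @param grid The [sim_grid()] the snapshot lives on.
#' @param fed_end `"left"` or `"right"`: the end the factor is fed from.
#' @param mid_width_only If `TRUE`, only the row(s) nearest mid-width are
#'   scanned (centre-line profile variant) instead of the full width.
#' @return Distance in mm.
#' @export
distribution_distance <- function(snapshot, ec50, grid,
                                  fed_end = c("left", "right"),
                                  mid_width_only = FALSE) {
  fed_end <- match.arg(fed_end)
  stopifnot(is.matrix(snapshot), nrow(snapshot) == grid$ny,
            ncol(snapshot) == grid$nx, ec50 > 0)
  if (mid_width_only) {
    mid <- unique(c(floor((grid$ny + 1) / 2), ceiling((grid$ny + 1) / 2)))
    snapshot <- snapshot[mid, , drop = FALSE]
  }
  active <- which(colSums(snapshot >= ec50) > 0)
  if (!length(active)) return(0)
  if (fed_end == "left") max(active) * grid$spacing
  else (grid$nx - min(active) + 1L) * grid$spacing
}

#' Maximum distribution distance and its time
#'
#' Scans every snapshot of a field for its bioactive extent
#' ([distribution_distance()]) and reports the maximum over time together
#' with the earliest snapshot time achieving it. Factors with a short
#' half-life peak soon after media addition and then recede; long-lived
#' factors keep spreading for days.
#'
#' @inheritParams distribution_distance
#' @param field A `concentration_field` with at least 2 snapshots.
#' @return List with `max_distance` (mm), `time_of_max` (s, earliest
#'   snapshot achieving the maximum), `time_max_ends` (s, the last snapshot
#'   still at the maximum: long-lived factors hold their maximal extent for
#'   days while short-lived ones recede within hours) and `distances`
#'   (mm per snapshot, named by hours).
#' @export
max_distribution <- function(field, ec50, fed_end = c("left", "right"),
                             mid_width_only = FALSE) {
  fed_end <- match.arg(fed_end)
  stopifnot(inherits(field, "concentration_field"), length(field$times) >= 2L)
  d <- vapply(seq_along(field$times), function(s)
    distribution_distance(field$values[, , s], ec50, field$grid, fed_end,
                          mid_width_only), numeric(1))
  at_max <- which(d == max(d))
  list(max_distance = max(d),
       time_of_max = field$times[at_max[1]],
       time_max_ends = field$times[at_max[length(at_max)]],
       distances = stats::setNames(d, sprintf("%.2f", field$times / 3600)))
}

#' Distribution report for one factor field
#'
#' Bundles the EC50-based design metrics for one factor: bioactive area
#' fraction over time, per-snapshot bioactive extent, and the maximum
#' distribution distance with its time.
#'
#' @inheritParams max_distribution
#' @param ec50 Bioactivity threshold; default the factor's EC50 from
#'   `factor_set`.
#' @param factor_set Named list of [growth_factor()] records.
#' @return An object of class `distribution_report`.
#' @export
distribution_report <- function(field, fed_end = c("left", "right"),
                                ec50 = NULL,
                                factor_set = default_growth_factors()) {
  fed_end <- match.arg(fed_end)
  if (is.null(ec50)) {
    if (!field$factor %in% names(factor_set))
      stop("no growth factor record for ", field$factor, call. = FALSE)
    ec50 <- factor_set[[field$factor]]$ec50
  }
  m <- max_distribution(field, ec50, fed_end)
  structure(list(factor = field$factor, fed_end = fed_end, ec50 = ec50,
                 max_distance = m$max_distance,
                 time_of_max = m$time_of_max,
                 time_max_ends = m$time_max_ends,
                 distances = m$distances,
                 bioactive_fraction = bioactive_fraction(field, ec50)),
            class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf(
    "<distribution_report> %s (fed %s): max distribution %.2f mm at %.1f h; peak bioactive fraction %.2f\n",
    x$factor, x$fed_end, x$max_distance, x$time_of_max / 3600,
    max(x$bioactive_fraction)))
  invisible(x)
}

#' Identify the distribution-limiting factor of a media
#'
#' Among the factors fed from one side of the chip, the limiting factor is
#' the one whose bioactive distribution reaches the shortest maximum
#' distance into the compartment — the factor that constrains how deep the
#' media's full biological activity extends.
#'
#' @param result A `simulation_result` from [simulate_media()].
#' @param side `"left"` or `"right"`: which media side to assess.
#' @param factor_set Named list of [growth_factor()] records (EC50s).
#' @return List with `factor` (the limiting factor's name) and
#'   `max_distances` (named mm vector for all factors fed from that side).
#' @export
limiting_factor <- function(result, side = c("left", "right"),
                            factor_set = default_growth_factors()) {
  side <- match.arg(side)
  stopifnot(inherits(result, "simulation_result"))
  fed <- names(result$media_pair[[side]]$factors)
  fed <- intersect(fed, names(result$fields))
  if (!length(fed))
    stop("no simulated factors are fed from the ", side, " side",
         call. = FALSE)
  d <- vapply(fed, function(f)
    max_distribution(result$fields[[f]], factor_set[[f]]$ec50,
                     fed_end = side)$max_distance, numeric(1))
  list(factor = names(d)[which.min(d)], max_distances = d)
}

#' Export distribution reports as JSON and CSV
#'
#' Writes a JSON summary (per factor: fed end, EC50, max distance in mm,
#' time of max in hours) and a CSV time series of bioactive extent and
#' area fraction per snapshot.
#'
#' @param reports List of `distribution_report` objects.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisible list of the paths written.
#' @export
write_distribution_reports <- function(reports, json_path = NULL,
                                       csv_path = NULL) {
  stopifnot(all(vapply(reports, inherits, logical(1), "distribution_report")))
  if (!is.null(json_path)) {
    summary <- lapply(reports, function(r)
      list(factor = r$factor, fed_end = r$fed_end, ec50_ng_ml = r$ec50,
           max_distance_mm = r$max_distance,
           time_of_max_h = r$time_of_max / 3600,
           time_max_ends_h = r$time_max_ends / 3600))
    names(summary) <- vapply(reports, `[[`, character(1), "factor")
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(reports, function(r)
      data.frame(factor = r$factor,
                 time_h = as.numeric(names(r$distances)),
                 distance_mm = as.numeric(r$distances),
                 bioactive_fraction = as.numeric(r$bioactive_fraction))))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(list(json = json_path, csv = csv_path))
}

#' Plot mid-width concentration profiles with EC50 extent markers
#'
#' Draws the concentration along the compartment length at mid-width for
#' each snapshot (lines darkening with time), normalised to the supplemented
#' concentration, with a vertical line marking the furthest bioactive
#' extent.
#'
#' @param field A `concentration_field`.
#' @param ec50 Bioactivity threshold (ng/mL).
#' @param c0 Supplemented concentration used for normalisation (ng/mL).
#' @param path Output PNG path.
#' @param fed_end Fed end for the extent marker.
#' @return `path`, invisibly.
#' @export
plot_profile <- function(field, ec50, c0, path, fed_end = "left") {
  stopifnot(inherits(field, "concentration_field"))
  mid <- ceiling(field$grid$ny / 2)
  nt <- length(field$times)
  cols <- grDevices::gray(seq(0.85, 0, length.out = nt))
  grDevices::png(path, width = 700, height = 450)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(NULL, xlim = range(field$grid$x), ylim = c(0, 1),
                 xlab = "x (mm)", ylab = "C / C0",
                 main = sprintf("%s mid-width profiles", field$factor))
  for (s in seq_len(nt))
    graphics::lines(field$grid$x, field$values[mid, , s] / c0,
                    col = cols[s])
  m <- max_distribution(field, ec50, fed_end)
  xline <- if (fed_end == "left") m$max_distance else
    field$geometry$length - m$max_distance
  graphics::abline(v = xline, col = "red", lty = 2)
  graphics::abline(h = ec50 / c0, col = "red", lty = 3)
  invisible(path)
}
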