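#' Chip culture-compartment geometry
#'
#' The culture compartment is a rectangle `length` x `width` (mm) of
#' hydrogel. Media channels sandwich the compartment from above and below
#' at each end, overlapping it for `channel_segment_length` mm of its
#' length; the rest of the boundary is impermeable wall. In the 2D
#' (plan-view) transport model the channel-overlap region at a fed end is
#' held at the channel concentration across the full compartment width
#' (`channel_style = "overlap"`, the default). The alternative
#' `"edge"` style instead clamps only the first and last grid rows over the
#' overlap span, for devices whose channels run alongside the gel in-plane
#' rather than over it.
#'
#' Each channel is fed by a reservoir; by default the two channels at the
#' left end share the `"left"` reservoir and the two at the right share
#' `"right"`, so media loaded at one end bathes both of its channels.
#'
#' @param length Compartment length (mm), x direction.
#' @param width Compartment width (mm), y direction.
#' @param channel_segment_length Length of each channel's overlap with the
#'   compartment (mm).
#' @param segments Data frame with columns `edge` ("top"/"bottom": above or
#'   below the gel), `end` ("left"/"right") and `reservoir` (reservoir id),
#'   one row per channel. Defaults to the four channels paired by end.
#' @param channel_style `"overlap"` (channels over/under the gel ends;
#'   full-width boundary region) or `"edge"` (in-plane channels; edge rows
#'   only).
#' @return An object of class `chip_geometry`.
#' @examples
#' chip_geometry()          # the default 1.3 x 7.9 mm compartment
#' @export
chip_geometry <- function(length = 7.9, width = 1.3,
                          channel_segment_length = 2.6,
                          segments = NULL,
                          channel_style = c("overlap", "edge")) {
  channel_style <- match.arg(channel_style)
  stopifnot(length > 0, width > 0, channel_segment_length > 0)
  if (2 * channel_segment_length > length + 1e-9)
    stop("channel segments overlap: 2 * channel_segment_length must be <= length",
         call. = FALSE)
  if (is.null(segments)) {
    segments <- data.frame(
      edge = c("top", "bottom", "top", "bottom"),
      end = c("left", "left", "right", "right"),
      reservoir = c("left", "left", "right", "right"),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(segments),
            all(c("edge", "end", "reservoir") %in% names(segments)),
            all(segments$edge %in% c("top", "bottom")),
            all(segments$end %in% c("left", "right")))
  structure(list(length = length, width = width,
                 channel_segment_length = channel_segment_length,
                 segments = segments, channel_style = channel_style),
            class = "chip_geometry")
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat(sprintf("<chip_geometry> %g x %g mm, %d channel segments of %g mm\n",
              x$length, x$width, nrow(x$segments),
              x$channel_segment_length))
  invisible(x)
}

#' Cell-centred finite-difference grid over the compartment
#'
#' Cells are square with side `spacing` (mm). Cell centres sit at
#' `(i - 0.5) * spacing` from the left end (x) and bottom edge (y). The
#' default 0.05 mm spacing discretises the default compartment into
#' 158 x 26 cells.
#'
#' @param geometry A [chip_geometry()].
#' @param spacing Grid spacing (mm).
#' @return An object of class `sim_grid` with fields `spacing`, `nx`, `ny`,
#'   `x` (cell-centre x coordinates, mm) and `y` (cell-centre y, mm).
#' @export
sim_grid <- function(geometry = chip_geometry(), spacing = 0.05) {
  stopifnot(inherits(geometry, "chip_geometry"), spacing > 0)
  nx <- max(1L, as.integer(round(geometry$length / spacing)))
  ny <- max(1L, as.integer(round(geometry$width / spacing)))
  if (ny < 2L)
    stop("grid too coarse: fewer than 2 cells across the compartment width",
         call. = FALSE)
  structure(list(spacing = spacing, nx = nx, ny = ny,
                 x = (seq_len(nx) - 0.5) * spacing,
                 y = (seq_len(ny) - 0.5) * spacing),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid> %d x %d cells at %g mm spacing\n",
              x$nx, x$ny, x$spacing))
  invisible(x)
}

# Map each channel segment onto the grid cells it clamps.
# Returns a list with one element per segment: list(rows, cols, reservoir).
# Rows follow the matrix convention used by the solver: row 1 is the bottom
# edge (y = 0), row ny the top edge. In "overlap" style a segment spans all
# rows over its length span (the channel lies over/under the gel); in
# "edge" style only the grid row adjacent to the channel.
segment_cells <- function(geometry, grid) {
  style <- geometry$channel_style %||% "overlap"
  lapply(seq_len(nrow(geometry$segments)), function(i) {
    seg <- geometry$segments[i, ]
    rows <- if (style == "overlap") seq_len(grid$ny)
            else if (seg$edge == "bottom") 1L else grid$ny
    # cells whose centre lies within the segment span
    if (seg$end == "left") {
      cols <- which(grid$x < geometry$channel_segment_length)
    } else {
      cols <- which(grid$x > geometry$length - geometry$channel_segment_length)
    }
    list(rows = rows, cols = cols, reservoir = seg$reservoir,
         edge = seg$edge, end = seg$end)
  })
}
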