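# Internal helpers: classed error conditions and small geometry utilities.

abort_wsis <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "wsis_error")))
}

stop_parameter <- function(msg) abort_wsis(msg, "wsis_parameter_error")
stop_bounds    <- function(msg) abort_wsis(msg, "wsis_bounds_error")
stop_format    <- function(msg) abort_wsis(msg, "wsis_format_error")
stop_degenerate <- function(msg) abort_wsis(msg, "wsis_degenerate_error")
stop_undefined  <- function(msg) abort_wsis(msg, "wsis_undefined_metric_error")
stop_input      <- function(msg) abort_wsis(msg, "wsis_input_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert level-0 pixels to microns
#'
#' @param px length in pixels.
#' @param microns_per_px physical resolution (default 0.49 micron/px, the
#'   Aperio 20x convention used throughout the package).
#' @return length in microns.
#' @export
px_to_microns <- function(px, microns_per_px = 0.49) {
  px * microns_per_px
}

# Points inside one or more polygons (union; even-odd rule via mgcv::in.out).
# `polys` is a single 2-col matrix or a list of them; pts an n x 2 matrix.
points_in_polys <- function(pts, polys) {
  if (is.matrix(polys)) polys <- list(polys)
  n <- nrow(pts)
  if (n == 0L) return(logical(0))
  inside <- logical(n)
  for (p in polys) {
    if (is.null(p) || nrow(p) < 3L) next
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- mgcv::in.out(
      rbind(unname(as.matrix(p)), c(NA, NA)),
      matrix(pts[todo, , drop = FALSE], ncol = 2)
    )
  }
  inside
}

# Shoelace signed area; > 0 means counter-clockwise in the mathematical
# (y-up) convention used for all stored polygons.
polygon_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}
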