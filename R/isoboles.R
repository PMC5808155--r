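#' Extract isoboles (iso-effect contours) from a surface model
#'
#' Isoboles are contours of constant response in the `(x1, x2)` dose
#' plane; linear isoboles are the classical signature of Loewe
#' Additivity.  The surface is evaluated on the supplied grid and
#' contours are extracted by linear interpolation on grid cells
#' (marching squares via [grDevices::contourLines()]).  Grid resolution
#' is the caller's responsibility: interpolation error shrinks with the
#' grid spacing and no adaptive refinement is attempted.
#'
#' @param model a [surface_model()].
#' @param levels response levels; each must lie strictly between the
#'   reachable minimum (`max(y_inf)` for the gi/mean kinds) and `y0` for
#'   a non-empty contour.  Levels outside the surface's range yield no
#'   polyline and are reported in the `"missing_levels"` attribute.
#' @param doses1,doses2 ascending dose grids (`length >= 2`).
#' @return A data frame of class `"isoboles"` with columns `level`,
#'   `segment_id` (contours can split into several polylines), `x1`,
#'   `x2`.
#' @examples
#' p <- curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
#' iso <- isoboles(surface_model("mean", p), 0.5,
#'                 seq(0, 4, 0.05), seq(0, 4, 0.05))
#' @export
isoboles <- function(model, levels, doses1, doses2) {
  stopifnot(length(doses1) >= 2, length(doses2) >= 2)
  z <- surface_matrix(model, doses1, doses2)
  cl <- grDevices::contourLines(x = doses1, y = doses2, z = z,
                                levels = levels)
  if (length(cl) == 0L) {
    out <- data.frame(level = numeric(), segment_id = integer(),
                      x1 = numeric(), x2 = numeric())
  } else {
    out <- do.call(rbind, lapply(seq_along(cl), function(i) {
      data.frame(level = cl[[i]]$level, segment_id = i,
                 x1 = cl[[i]]$x, x2 = cl[[i]]$y)
    }))
  }
  found <- unique(out$level)
  missing <- levels[!vapply(levels, function(l)
    any(abs(found - l) < 1e-12), TRUE)]
  attr(out, "missing_levels") <- missing
  class(out) <- c("isoboles", "data.frame")
  out
}

#' Deviation of a polyline from its straight chord
#'
#' Measures how far a contour bends: the maximum perpendicular distance
#' from the points to the straight chord joining the endpoints, divided
#' by the chord length.  Straight Loewe isoboles give values at the
#' interpolation-noise floor; curved explicit-model isoboles give
#' visibly larger values.
#'
#' @param x1,x2 coordinates of the polyline points (in order).
#' @return A single number: max perpendicular deviation / chord length.
#' @export
chord_deviation <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  p1 <- c(x1[1], x2[1]); p2 <- c(x1[length(x1)], x2[length(x2)])
  v <- p2 - p1
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate chord: endpoints coincide")
  d <- abs(v[1] * (x2 - p1[2]) - v[2] * (x1 - p1[1])) / len
  max(d) / len
}
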