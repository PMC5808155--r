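#' Four-parameter log-logistic (Hill) dose-response curve
#'
#' Constructs a Hill curve in the four-parameter log-logistic
#' parameterization
#' \deqn{f(x) = y_\infty + \frac{y_0 - y_\infty}{1 + (x/e)^s},}
#' the standard model for inhibitory dose-response data: `y0` is the
#' response at zero dose, `y_inf` the asymptotic response at infinite dose
#' (the maximal effect), `e` the dose reaching half of the maximal effect
#' (EC50), and `s` the slope.  With `s > 0` and `y0 > y_inf` the curve is
#' strictly decreasing, the orientation assumed throughout (responses are
#' viability/growth fractions, so larger dose means smaller response).
#'
#' @param y0 response at zero dose.
#' @param y_inf asymptotic response at infinite dose; must satisfy
#'   `y_inf < y0`.
#' @param e half-maximal-effect dose, in the dose units of the record the
#'   curve was fitted to; must be positive.
#' @param s slope (dimensionless); must be positive.
#'
#' @return An object of class `"hill_curve"`.
#' @seealso [hill_response()], [hill_inverse()], [curve_pair()]
#' @examples
#' crv <- hill_curve(y0 = 1, y_inf = 0, e = 1, s = 2)
#' hill_response(crv, c(0, 1, Inf))
#' @export
hill_curve <- function(y0, y_inf, e, s) {
  stopifnot(is.numeric(y0), is.numeric(y_inf), is.numeric(e), is.numeric(s),
            length(y0) == 1L, length(y_inf) == 1L, length(e) == 1L,
            length(s) == 1L)
  if (!is.finite(e) || e <= 0) stop("'e' (EC50) must be finite and positive")
  if (!is.finite(s) || s <= 0) stop("'s' (slope) must be finite and positive")
  if (!(y0 > y_inf)) stop("'y0' must exceed 'y_inf' (decreasing orientation)")
  new_hill_curve(y0, y_inf, e, s)
}

# Unvalidated constructor: fitting may produce curves that violate the
# invariants (e.g. negative slope); those are represented but flagged for
# exclusion rather than erroring at construction.
new_hill_curve <- function(y0, y_inf, e, s) {
  structure(list(y0 = as.numeric(y0), y_inf = as.numeric(y_inf),
                 e = as.numeric(e), s = as.numeric(s)),
            class = "hill_curve")
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve: y0 = %.6g, y_inf = %.6g, e = %.6g, s = %.6g\n",
              x$y0, x$y_inf, x$e, x$s))
  invisible(x)
}

#' Evaluate a Hill curve
#'
#' Computes the response at dose `x`.  The dose-zero term `(x/e)^s` is
#' defined as 0 at `x = 0`, so `hill_response(crv, 0)` returns `y0`
#' exactly; `x = Inf` returns `y_inf`.
#'
#' @param curve a [hill_curve()].
#' @param x numeric vector of doses, each `>= 0` (or `Inf`).
#' @return Numeric vector of responses.
#' @export
hill_response <- function(curve, x) {
  x <- as.numeric(x)
  if (any(is.nan(x)) || any(x < 0, na.rm = TRUE))
    stop("doses must be non-negative")
  t <- (x / curve$e)^curve$s
  t[x == 0] <- 0        # exact y0 at zero dose, any slope
  curve$y_inf + (curve$y0 - curve$y_inf) / (1 + t)
}

#' Invert a Hill curve
#'
#' Closed-form inverse of the four-parameter log-logistic curve:
#' \eqn{f^{-1}(y) = e\,((y_0 - y)/(y - y_\infty))^{1/s}}.  Returns 0 at
#' `y = y0` and `Inf` for `y <= y_inf` (the effect is unreachable at any
#' finite dose).  Responses above `y0` have no non-negative dose and raise
#' an error; values within a small numerical tolerance of `y0` are clamped
#' to `y0`.
#'
#' @param curve a [hill_curve()].
#' @param y numeric vector of responses.
#' @return Numeric vector of doses (possibly `Inf`).
#' @export
hill_inverse <- function(curve, y) {
  y <- as.numeric(y)
  y0 <- curve$y0; yi <- curve$y_inf
  tol <- 1e-9 * (y0 - yi)
  if (any(y > y0 + tol, na.rm = TRUE))
    stop("response above y0: dose would be negative")
  y <- pmin(y, y0)
  out <- rep(Inf, length(y))
  at0 <- y == y0
  mid <- !at0 & y > yi
  out[at0] <- 0
  out[mid] <- curve$e * ((y0 - y[mid]) / (y[mid] - yi))^(1 / curve$s)
  out
}

#' Pair of Hill curves sharing the zero-dose response
#'
#' The unit on which all null-reference surfaces are defined: the two
#' conditional (single-compound) dose-response curves of a record.  Both
#' curves must share the same response at zero dose (they describe the
#' same untreated wells); dose units may differ between the two compounds
#' and are never converted.
#'
#' @param curve1,curve2 [hill_curve()] objects with equal `y0` (within
#'   `tol`).
#' @param tol absolute tolerance on the shared `y0`.
#' @return An object of class `"curve_pair"`.
#' @examples
#' p <- curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
#' @export
curve_pair <- function(curve1, curve2, tol = 1e-8) {
  stopifnot(inherits(curve1, "hill_curve"), inherits(curve2, "hill_curve"))
  if (abs(curve1$y0 - curve2$y0) > tol)
    stop("curves must share the zero-dose response y0")
  # store the common y0 on both curves so f2(0) inverts to exactly 0 under f1
  y0 <- (curve1$y0 + curve2$y0) / 2
  curve1$y0 <- y0; curve2$y0 <- y0
  structure(list(curve1 = curve1, curve2 = curve2), class = "curve_pair")
}

#' Swap the compounds of a curve pair
#'
#' @param pair a [curve_pair()].
#' @return The pair with `curve1` and `curve2` exchanged.
#' @export
swap_pair <- function(pair) {
  stopifnot(inherits(pair, "curve_pair"))
  structure(list(curve1 = pair$curve2, curve2 = pair$curve1),
            class = "curve_pair")
}

#' @export
print.curve_pair <- function(x, ...) {
  cat("Curve pair (shared y0 =", format(x$curve1$y0, digits = 6), ")\n")
  cat("  compound 1: "); print(x$curve1)
  cat("  compound 2: "); print(x$curve2)
  invisible(x)
}
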