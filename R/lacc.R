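#' Effect-equivalent doses
#'
#' Under Loewe Additivity, a dose of one compound can be replaced by the
#' dose of the other compound producing the same response.
#' `equivalent_dose_1(pair, x2)` is the dose of compound 1 equivalent to
#' dose `x2` of compound 2, \eqn{f_1^{-1}(f_2(x_2))};
#' `equivalent_dose_2(pair, x1)` is its mirror
#' \eqn{f_2^{-1}(f_1(x_1))}.  When the response reached by one compound
#' lies below the other compound's maximal effect, no finite equivalent
#' exists and `Inf` is returned.
#'
#' @param pair a [curve_pair()].
#' @param x1,x2 numeric vector of doses, `>= 0`.
#' @return Numeric vector of equivalent doses (possibly `Inf`).
#' @examples
#' p <- curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
#' equivalent_dose_1(p, 2)  # = 1: the curves differ only in EC50
#' @export
equivalent_dose_1 <- function(pair, x2) {
  hill_inverse(pair$curve1, hill_response(pair$curve2, x2))
}

#' @rdname equivalent_dose_1
#' @export
equivalent_dose_2 <- function(pair, x1) {
  hill_inverse(pair$curve2, hill_response(pair$curve1, x1))
}

#' Check the Loewe Additivity Consistency Condition for a curve pair
#'
#' The consistency condition (LACC) requires the two substitution orders
#' to agree everywhere: replacing compound 1 by its compound-2 equivalent
#' must give the same surface as the reverse.  For Hill curves this holds
#' exactly when the two curves differ only in their half-effect dose `e`
#' (equal `y0`, `y_inf` and slope), in which case equivalent doses are
#' proportional with constant `e1/e2` and the conditional curves are
#' horizontally shifted copies on the log-dose axis.
#'
#' The parameter test compares slopes and asymptotes at relative
#' tolerance `param_tol`; the surface asymmetry
#' \eqn{\max |f_{2\to1} - f_{1\to2}|} is measured on a dose grid (a
#' finite surrogate for the "for all doses" condition).  By default the
#' grid spans `[0, 4 e]` per axis with 20 points; pass `doses1`/`doses2`
#' (e.g. the record's own design) to override.
#'
#' @param pair a [curve_pair()].
#' @param doses1,doses2 optional dose grids for the asymmetry measure.
#' @param param_tol relative tolerance for the parameter comparison.
#' @return An object of class `"lacc_report"`: list with `proportional`
#'   (logical: parameter criterion satisfied), `c_hat` (estimated
#'   proportionality constant `e1/e2`; dimensionless only if both dose
#'   axes share units — see `units_caveat`), `max_asymmetry` (response
#'   units), `grid_spec`, `units_caveat`.
#' @examples
#' p <- curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
#' check_lacc(p)$proportional
#' @export
check_lacc <- function(pair, doses1 = NULL, doses2 = NULL,
                       param_tol = 1e-6) {
  c1 <- pair$curve1; c2 <- pair$curve2
  if (is.null(doses1)) doses1 <- seq(0, 4 * c1$e, length.out = 20)
  if (is.null(doses2)) doses2 <- seq(0, 4 * c2$e, length.out = 20)
  span <- c1$y0 - max(c1$y_inf, c2$y_inf)
  s_ok <- abs(c1$s - c2$s) <= param_tol * max(abs(c1$s), abs(c2$s))
  yi_ok <- abs(c1$y_inf - c2$y_inf) <= param_tol * span
  y0_ok <- abs(c1$y0 - c2$y0) <= param_tol * span
  g <- expand.grid(x1 = doses1, x2 = doses2)
  asym <- max(abs(explicit_2to1(pair, g$x1, g$x2) -
                  explicit_1to2(pair, g$x1, g$x2)))
  structure(list(proportional = s_ok && yi_ok && y0_ok,
                 c_hat = c1$e / c2$e,
                 max_asymmetry = asym,
                 grid_spec = list(doses1 = doses1, doses2 = doses2),
                 units_caveat = paste("c_hat is a ratio of the two EC50s;",
                                      "it is dimensionless only if both dose",
                                      "axes share the same unit")),
            class = "lacc_report")
}

#' @export
print.lacc_report <- function(x, ...) {
  cat(sprintf("LACC report: proportional = %s, c_hat = %.6g, max asymmetry = %.3g\n",
              x$proportional, x$c_hat, x$max_asymmetry))
  invisible(x)
}

#' Population-level test of the consistency condition
#'
#' Across a set of fitted records, the LACC predicts equal slopes and
#' equal maximal effects between the two conditional curves of each
#' record.  This applies paired Wilcoxon signed-rank tests to the
#' per-record slope pairs \eqn{(s_1, s_2)} and asymptote pairs
#' \eqn{(y_{\infty,1}, y_{\infty,2})}; small p-values indicate systematic
#' violation in the population.  Excluded fits are dropped.  Zero
#' differences are discarded by the signed-rank convention; if all
#' differences are zero the p-value is 1 by convention and the result is
#' flagged degenerate.
#'
#' @param fits a list of [fit_pair()] results (or of [curve_pair()]
#'   objects).
#' @param alternative passed to [stats::wilcox.test()]; the default
#'   two-sided matches the exploratory question "are they different".
#' @return A list of class `"population_lacc_test"` with `p_slope`,
#'   `p_yinf`, `n_records`, `degenerate`.
#' @export
population_lacc_test <- function(fits, alternative = "two.sided") {
  pairs <- lapply(fits, function(f) {
    if (inherits(f, "pair_fit")) {
      if (isTRUE(f$excluded)) return(NULL)
      f$pair
    } else if (inherits(f, "curve_pair")) f
    else stop("fits must contain 'pair_fit' or 'curve_pair' objects")
  })
  pairs <- Filter(Negate(is.null), pairs)
  n <- length(pairs)
  if (n < 1L) stop("no usable (non-excluded) fits")
  s1 <- vapply(pairs, function(p) p$curve1$s, 0)
  s2 <- vapply(pairs, function(p) p$curve2$s, 0)
  yi1 <- vapply(pairs, function(p) p$curve1$y_inf, 0)
  yi2 <- vapply(pairs, function(p) p$curve2$y_inf, 0)
  wtest <- function(a, b) {
    if (all(a == b)) return(list(p = 1, degenerate = TRUE))
    p <- suppressWarnings(
      stats::wilcox.test(a, b, paired = TRUE, alternative = alternative,
                         exact = FALSE))$p.value
    list(p = p, degenerate = FALSE)
  }
  ws <- wtest(s1, s2); wy <- wtest(yi1, yi2)
  structure(list(p_slope = ws$p, p_yinf = wy$p, n_records = n,
                 degenerate = ws$degenerate && wy$degenerate,
                 alternative = alternative),
            class = "population_lacc_test")
}

#' @export
print.population_lacc_test <- function(x, ...) {
  cat(sprintf("Population LACC test (n = %d, %s): p_slope = %.3g, p_yinf = %.3g%s\n",
              x$n_records, x$alternative, x$p_slope, x$p_yinf,
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  invisible(x)
}
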