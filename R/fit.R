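#' Fit a constrained Hill-curve pair to two conditional series
#'
#' Fits the two conditional (single-compound) dose-response series of a
#' record with four-parameter log-logistic curves that share the
#' zero-dose response `y0`: seven free parameters in total (one `y0`,
#' plus `y_inf`, `e`, `s` per compound), minimizing the unweighted sum of
#' squared residuals over both series jointly by Levenberg-Marquardt
#' least squares.  `e` is optimized on the log10 scale for conditioning.
#'
#' Starting values are a deterministic multistart grid: the slope is
#' started at each of `s_starts` (shared by both curves), while `y0`,
#' `y_inf` and `e` start from data-driven values (mean response at zero
#' dose, minimum response per series, and the positive dose whose
#' response is closest to the half-way point).  The best final SSR wins;
#' ties go to the earlier grid entry.  The procedure is deterministic
#' given the data.
#'
#' Fits with a non-positive slope or a non-positive EC50 in either curve
#' are marked `excluded` with a reason; such records cannot support a
#' decreasing-response null model.  Other pathologies (e.g. a fitted
#' `y_inf` above `y0`) are flagged in the returned object but not
#' excluded.
#'
#' @param cond1,cond2 data frames (or lists) with columns `dose` and
#'   `response`: the conditional series of compounds 1 and 2.  Each needs
#'   at least 4 points including dose 0.
#' @param s_starts numeric vector of slope starting values.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return An object of class `"pair_fit"`: a list with elements `pair`
#'   (a [curve_pair()] built without validation), `converged`, `loss`
#'   (final SSR), `excluded`, `reason`, `flags` (character vector of
#'   non-excluding pathologies), and `n_points`.
#' @examples
#' crv <- hill_curve(1, 0, 1, 2)
#' d <- c(0, 2^(-3:3))
#' fit <- fit_pair(data.frame(dose = d, response = hill_response(crv, d)),
#'                 data.frame(dose = d, response = hill_response(crv, d)))
#' fit$pair
#' @export
fit_pair <- function(cond1, cond2, s_starts = c(0.5, 1, 2, 4),
                     control = minpack.lm::nls.lm.control(maxiter = 100)) {
  c1 <- check_conditional(cond1, "cond1")
  c2 <- check_conditional(cond2, "cond2")
  n_points <- nrow(c1) + nrow(c2)
  if (n_points < 7L) stop("fewer data points than free parameters (7)")

  d1 <- c1$dose; r1 <- c1$response
  d2 <- c2$dose; r2 <- c2$response
  z1 <- d1 == 0; z2 <- d2 == 0

  # residuals for par = (y0, yinf1, log10 e1, s1, yinf2, log10 e2, s2)
  resid_fun <- function(par) {
    y0 <- par[1]
    t1 <- (d1 / 10^par[3])^par[4]; t1[z1] <- 0
    t2 <- (d2 / 10^par[6])^par[7]; t2[z2] <- 0
    p1 <- par[2] + (y0 - par[2]) / (1 + t1)
    p2 <- par[5] + (y0 - par[5]) / (1 + t2)
    v <- c(r1 - p1, r2 - p2)
    v[!is.finite(v)] <- 1e6
    v
  }

  y0_start <- mean(c(r1[z1], r2[z2]))
  e_start <- function(d, r, y0s) {
    pos <- d > 0
    half <- (y0s + min(r)) / 2
    d[pos][which.min(abs(r[pos] - half))]
  }
  le1 <- log10(e_start(d1, r1, y0_start))
  le2 <- log10(e_start(d2, r2, y0_start))

  best <- NULL
  for (s0 in s_starts) {
    par0 <- c(y0_start, min(r1), le1, s0, min(r2), le2, s0)
    # poor starts may exhaust maxiter with a warning; the multistart keeps
    # the best SSR, so those are expected and silenced
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, fn = resid_fun, control = control)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || ssr < best$ssr - 1e-14)
      best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) stop("all fit starts failed")

  par <- best$fit$par
  curve1 <- new_hill_curve(par[1], par[2], 10^par[3], par[4])
  curve2 <- new_hill_curve(par[1], par[5], 10^par[6], par[7])
  pair <- structure(list(curve1 = curve1, curve2 = curve2),
                    class = "curve_pair")

  excluded <- FALSE; reason <- NA_character_
  bad_s <- c(curve1$s <= 0, curve2$s <= 0)
  bad_e <- c(curve1$e <= 0, curve2$e <= 0)
  if (any(bad_s)) {
    excluded <- TRUE
    reason <- sprintf("negative or zero slope for compound %s",
                      paste(which(bad_s), collapse = " and "))
  } else if (any(bad_e)) {
    excluded <- TRUE
    reason <- sprintf("negative or zero EC50 for compound %s",
                      paste(which(bad_e), collapse = " and "))
  }
  flags <- character()
  if (curve1$y_inf >= curve1$y0) flags <- c(flags, "curve1: y_inf >= y0")
  if (curve2$y_inf >= curve2$y0) flags <- c(flags, "curve2: y_inf >= y0")

  structure(list(pair = pair,
                 converged = best$fit$info %in% 1:4,
                 loss = best$ssr,
                 excluded = excluded,
                 reason = reason,
                 flags = flags,
                 n_points = n_points),
            class = "pair_fit")
}

check_conditional <- function(x, what) {
  x <- as.data.frame(x)
  if (!all(c("dose", "response") %in% names(x)))
    stop(what, " needs columns 'dose' and 'response'")
  x <- x[stats::complete.cases(x[c("dose", "response")]), , drop = FALSE]
  if (nrow(x) < 4L) stop(what, " needs at least 4 points")
  if (!any(x$dose == 0)) stop(what, " must include dose 0")
  if (any(x$dose < 0)) stop(what, " has negative doses")
  if (any(!is.finite(x$response))) stop(what, " has non-finite responses")
  x
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf("Hill pair fit: SSR = %.4g, converged = %s\n",
              x$loss, x$converged))
  if (x$excluded) cat("  EXCLUDED:", x$reason, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$pair)
  invisible(x)
}
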