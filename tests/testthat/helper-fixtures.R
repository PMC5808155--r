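# Canonical illustration parameter sets used throughout the tests:
# a consistent pair differing only in EC50, and the three ways the
# consistency condition breaks (slopes, asymptotes, both).
fig_lacc_pair <- function() {
  curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
}
fig_slopes_pair <- function() {
  curve_pair(hill_curve(1, 0, 1, 1), hill_curve(1, 0, 1, 2))
}
fig_maxeff_pair <- function() {
  curve_pair(hill_curve(1, 0.3, 1, 1), hill_curve(1, 0, 1, 1))
}
fig_both_pair <- function() {
  curve_pair(hill_curve(1, 0.3, 1, 1), hill_curve(1, 0, 1, 2))
}

# random valid decreasing Hill curve (uses current RNG stream)
random_curve <- function(y0 = 1) {
  hill_curve(y0, runif(1, 0, 0.4), exp(runif(1, log(0.25), log(4))),
             runif(1, 0.5, 4))
}

# random pair satisfying the consistency condition: shared y0/y_inf/s,
# independent EC50s
random_lacc_pair <- function() {
  yi <- runif(1, 0, 0.4); s <- runif(1, 0.5, 4)
  curve_pair(hill_curve(1, yi, exp(runif(1, log(0.25), log(4))), s),
             hill_curve(1, yi, exp(runif(1, log(0.25), log(4))), s))
}

# noiseless conditional series on a geometric dose grid
geometric_conditionals <- function(pair, n = 8) {
  mk <- function(crv) {
    d <- c(0, crv$e * 2^seq(-3, 3, length.out = n - 1))
    data.frame(dose = d, response = hill_response(crv, d))
  }
  list(cond1 = mk(pair$curve1), cond2 = mk(pair$curve2))
}

# independent dense-scan oracle for the implicit model: pick the y among
# n_scan evenly spaced candidates whose isobole sum is closest to 1.
# Computed straight from the curve parameters, including the
# unreachable-effect rule (one compound's response below the other's
# asymptote has no equivalent dose; the driving conditional wins), which
# is part of the model's definition, not of the solver.
gi_scan_oracle <- function(pair, x1, x2, n_scan = 1e6) {
  c1 <- pair$curve1; c2 <- pair$curve2
  hr <- function(crv, x) crv$y_inf + (crv$y0 - crv$y_inf) / (1 + (x / crv$e)^crv$s)
  if (x2 > 0 && hr(c2, x2) <= c1$y_inf) return(hr(c2, x2))
  if (x1 > 0 && hr(c1, x1) <= c2$y_inf) return(hr(c1, x1))
  y0 <- c1$y0
  lo <- max(c1$y_inf, c2$y_inf)
  ys <- seq(lo + 1e-12, y0 - 1e-12, length.out = n_scan)
  g <- x1 / hill_inverse(c1, ys) + x2 / hill_inverse(c2, ys) - 1
  ys[which.min(abs(g))]
}
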