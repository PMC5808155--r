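#' Solver settings for the implicit General Isobole model
#'
#' @param y_tol absolute tolerance on the solved response (bisection stops
#'   when the bracket is narrower than this).
#' @param max_iter iteration cap for the bisection.
#' @param bracket_pad relative padding applied to the response bracket
#'   `(max(y_inf), y0)` to keep the inverses finite at the endpoints.
#' @return A list of class `"solver_config"`.
#' @export
solver_config <- function(y_tol = 1e-9, max_iter = 200L, bracket_pad = 1e-12) {
  stopifnot(y_tol > 0, max_iter >= 1, bracket_pad > 0)
  structure(list(y_tol = y_tol, max_iter = as.integer(max_iter),
                 bracket_pad = bracket_pad),
            class = "solver_config")
}

#' General Isobole null-reference response
#'
#' The classical implicit Loewe Additivity model: the predicted response
#' `y` at dose combination `(x1, x2)` solves
#' \deqn{\frac{x_1}{f_1^{-1}(y)} + \frac{x_2}{f_2^{-1}(y)} = 1.}
#' The left-hand side is strictly increasing in `y` for decreasing Hill
#' curves, so the root is unique and is found by bracketed bisection on
#' `(max(y_inf1, y_inf2), y0)`.  Axis points return the conditional
#' responses exactly.  When one compound's response at its dose lies at or
#' below the other compound's asymptote, the effect has no equivalent and
#' the standard fallback applies: the term of the unreachable compound is
#' dropped, so the prediction equals the conditional response of the
#' compound driving the effect (`f2(x2)` when
#' `f2(x2) <= y_inf1`, mirrored for the other side; ties within `y_tol`
#' are routed to the fallback to avoid an unbounded inverse).
#'
#' @param pair a [curve_pair()].
#' @param x1,x2 numeric dose vectors (recycled to common length).
#' @param cfg a [solver_config()].
#' @return Numeric vector of predicted responses.
#' @examples
#' p <- curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
#' general_isobole(p, 1, 2)  # 0.2: with proportional curves, f1(x1 + x2*e1/e2)
#' @export
general_isobole <- function(pair, x1, x2, cfg = solver_config()) {
  n <- max(length(x1), length(x2))
  x1 <- rep_len(as.numeric(x1), n); x2 <- rep_len(as.numeric(x2), n)
  if (any(x1 < 0) || any(x2 < 0)) stop("doses must be non-negative")
  c1 <- pair$curve1; c2 <- pair$curve2
  f1x <- hill_response(c1, x1); f2x <- hill_response(c2, x2)
  y0 <- c1$y0
  yimax <- max(c1$y_inf, c2$y_inf)
  out <- rep(NA_real_, n)

  ax2 <- x2 == 0; ax1 <- x1 == 0 & !ax2
  out[ax2] <- f1x[ax2]
  out[ax1] <- f2x[ax1]
  open <- is.na(out)
  fb2 <- open & f2x <= c1$y_inf + cfg$y_tol
  out[fb2] <- f2x[fb2]
  open <- is.na(out)
  fb1 <- open & f1x <= c2$y_inf + cfg$y_tol
  out[fb1] <- f1x[fb1]

  todo <- which(is.na(out))
  if (length(todo)) {
    pad <- cfg$bracket_pad * (y0 - yimax)
    # per-combination root finding: the implicit model has no closed form,
    # each cell needs its own bracketed solve
    inv1 <- function(y) c1$e * ((y0 - y) / (y - c1$y_inf))^(1 / c1$s)
    inv2 <- function(y) c2$e * ((y0 - y) / (y - c2$y_inf))^(1 / c2$s)
    for (k in todo) {
      lo <- yimax + pad
      hi <- y0 - pad
      xa <- x1[k]; xb <- x2[k]
      iter <- 0L
      while (hi - lo > cfg$y_tol && iter < cfg$max_iter) {
        mid <- (lo + hi) / 2
        if (xa / inv1(mid) + xb / inv2(mid) > 1) hi <- mid else lo <- mid
        iter <- iter + 1L
      }
      if (hi - lo > cfg$y_tol)
        stop(sprintf(paste0("general isobole solver did not converge in %d ",
                            "iterations; last bracket [%.12g, %.12g] at ",
                            "(x1 = %g, x2 = %g)"),
                     cfg$max_iter, lo, hi, xa, xb))
      out[k] <- (lo + hi) / 2
    }
  }
  out
}

#' Explicit equivalent-dose null-reference surfaces
#'
#' The explicit Loewe models obtained by substituting one compound's dose
#' by its effect-equivalent dose of the other:
#' \deqn{f_{2\to1}(x_1, x_2) = f_1(x_1 + f_1^{-1}(f_2(x_2))), \qquad
#'       f_{1\to2}(x_1, x_2) = f_2(f_2^{-1}(f_1(x_1)) + x_2).}
#' When the equivalent dose is infinite (the other compound cannot reach
#' the effect), the substituted dose dominates and the prediction falls
#' back to the conditional response of the driving compound,
#' e.g. \eqn{f_{2\to1} = f_2(x_2)} when `f2(x2)` lies below compound 1's
#' asymptote.  Unlike the implicit model these are closed-form.
#'
#' @inheritParams general_isobole
#' @return Numeric vector of predicted responses.
#' @examples
#' p <- curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2))
#' explicit_2to1(p, 1, 2)  # 0.2, equal to the General Isobole here
#' @export
explicit_2to1 <- function(pair, x1, x2) {
  n <- max(length(x1), length(x2))
  x1 <- rep_len(as.numeric(x1), n); x2 <- rep_len(as.numeric(x2), n)
  if (any(x1 < 0) || any(x2 < 0)) stop("doses must be non-negative")
  explicit_2to1_core(pair, x1, x2)
}

#' @rdname explicit_2to1
#' @export
explicit_1to2 <- function(pair, x1, x2) {
  n <- max(length(x1), length(x2))
  x1 <- rep_len(as.numeric(x1), n); x2 <- rep_len(as.numeric(x2), n)
  if (any(x1 < 0) || any(x2 < 0)) stop("doses must be non-negative")
  explicit_1to2_core(pair, x1, x2)
}

# unvalidated cores: arguments already recycled and checked
explicit_2to1_core <- function(pair, x1, x2) {
  d <- equivalent_dose_1(pair, x2)
  out <- numeric(length(d))
  fin <- is.finite(d)
  out[fin] <- hill_response(pair$curve1, x1[fin] + d[fin])
  out[!fin] <- hill_response(pair$curve2, x2[!fin])
  out
}

explicit_1to2_core <- function(pair, x1, x2) {
  d <- equivalent_dose_2(pair, x1)
  out <- numeric(length(d))
  fin <- is.finite(d)
  out[fin] <- hill_response(pair$curve2, d[fin] + x2[fin])
  out[!fin] <- hill_response(pair$curve1, x1[!fin])
  out
}

#' Explicit mean null-reference surface
#'
#' The symmetric explicit model: the pointwise mean of the two
#' substitution-order surfaces,
#' \eqn{f_{mean} = \tfrac12 (f_{2\to1} + f_{1\to2})}.  It equals the
#' General Isobole surface whenever the consistency condition holds and
#' stays close to it under mild violations, at closed-form cost.  The
#' unequal-maximal-effect fallbacks of the component surfaces carry
#' through automatically.  A geometric-mean variant
#' (\eqn{\sqrt{f_{2\to1} f_{1\to2}}}) is provided; responses are floored
#' at 0 before the product so the root is defined.
#'
#' @inheritParams general_isobole
#' @param variant `"arithmetic"` (default) or `"geometric"`.
#' @return Numeric vector of predicted responses.
#' @export
explicit_mean <- function(pair, x1, x2,
                          variant = c("arithmetic", "geometric")) {
  variant <- match.arg(variant)
  n <- max(length(x1), length(x2))
  x1 <- rep_len(as.numeric(x1), n); x2 <- rep_len(as.numeric(x2), n)
  if (any(x1 < 0) || any(x2 < 0)) stop("doses must be non-negative")
  a <- explicit_2to1_core(pair, x1, x2)
  b <- explicit_1to2_core(pair, x1, x2)
  if (variant == "arithmetic") (a + b) / 2
  else sqrt(pmax(a, 0) * pmax(b, 0))
}

#' Null-reference surface model
#'
#' Binds one of the five null-model kinds to a curve pair (and, for the
#' implicit `"gi"` kind, to solver settings), giving a single evaluator
#' object for downstream checkerboard prediction, isobole extraction and
#' residual analysis.
#'
#' @param kind one of `"gi"` (implicit General Isobole), `"2to1"`,
#'   `"1to2"` (explicit substitution orders), `"mean"` (arithmetic
#'   explicit mean, the default explicit model), `"geomean"`.
#' @param pair a [curve_pair()].
#' @param solver a [solver_config()]; used only by `"gi"`.
#' @return An object of class `"surface_model"`.
#' @seealso [evaluate_surface()], [surface_matrix()], [isoboles()]
#' @export
surface_model <- function(kind = c("gi", "2to1", "1to2", "mean", "geomean"),
                          pair, solver = solver_config()) {
  kind <- match.arg(kind)
  stopifnot(inherits(pair, "curve_pair"), inherits(solver, "solver_config"))
  structure(list(kind = kind, pair = pair, solver = solver),
            class = "surface_model")
}

#' Evaluate a surface model at dose combinations
#'
#' @param model a [surface_model()].
#' @param x1,x2 numeric dose vectors (recycled).
#' @return Numeric vector of predicted responses.
#' @export
evaluate_surface <- function(model, x1, x2) {
  switch(model$kind,
         gi      = general_isobole(model$pair, x1, x2, model$solver),
         "2to1"  = explicit_2to1(model$pair, x1, x2),
         "1to2"  = explicit_1to2(model$pair, x1, x2),
         mean    = explicit_mean(model$pair, x1, x2, "arithmetic"),
         geomean = explicit_mean(model$pair, x1, x2, "geometric"))
}

#' Predicted response matrix on a checkerboard
#'
#' Evaluates the model on the full dose grid: `M[i, j]` is the prediction
#' at `(doses1[i], doses2[j])`, so the first row and column reproduce the
#' conditional curves when the grids start at 0.
#'
#' @param model a [surface_model()].
#' @param doses1,doses2 ascending dose vectors (length `>= 1`).
#' @return A numeric matrix with doses as dimnames.
#' @export
surface_matrix <- function(model, doses1, doses2) {
  stopifnot(length(doses1) >= 1, length(doses2) >= 1)
  if (is.unsorted(doses1) || is.unsorted(doses2))
    stop("doses must be sorted ascending")
  x1 <- rep(doses1, times = length(doses2))
  x2 <- rep(doses2, each = length(doses1))
  matrix(evaluate_surface(model, x1, x2),
         nrow = length(doses1), ncol = length(doses2),
         dimnames = list(as.character(doses1), as.character(doses2)))
}

#' @export
print.surface_model <- function(x, ...) {
  cat("Null-reference surface model:", x$kind, "\n")
  print(x$pair)
  invisible(x)
}
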