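#' Checkerboard dose designs
#'
#' `dose_design()` builds a design from explicit dose vectors; both axes
#' must start at exactly 0 and increase strictly.  Two standard
#' high-throughput layouts are provided as helpers:
#' `dilution6_design()`, a 6-dose series per axis consisting of a top
#' dose followed by four 4-fold dilutions plus a zero dose (the layout
#' of one-to-all 6x6 viability screens); and `linear8_design()`, 8 doses
#' evenly spaced from 0 to the top dose (the layout of 8x8 factorial
#' growth screens).  Doses are stored ascending with 0 first.
#'
#' @param doses1,doses2 ascending numeric dose vectors starting at 0.
#' @param name design label.
#' @return An object of class `"dose_design"`.
#' @examples
#' dilution6_design(2.5, 125)$doses1  # 0, 2.5/256, ..., 2.5
#' @export
dose_design <- function(doses1, doses2, name = "custom") {
  check_doses <- function(d, what) {
    d <- as.numeric(d)
    if (length(d) < 1 || d[1] != 0)
      stop(what, " must start at exactly 0")
    if (any(diff(d) <= 0)) stop(what, " must be strictly increasing")
    d
  }
  structure(list(doses1 = check_doses(doses1, "doses1"),
                 doses2 = check_doses(doses2, "doses2"),
                 design_name = name),
            class = "dose_design")
}

#' @rdname dose_design
#' @param dmax1,dmax2 top dose per axis.
#' @export
dilution6_design <- function(dmax1, dmax2) {
  series <- function(dmax) c(0, dmax / 4^(4:0))
  dose_design(series(dmax1), series(dmax2), name = "dilution6")
}

#' @rdname dose_design
#' @export
linear8_design <- function(dmax1, dmax2) {
  dose_design(seq(0, dmax1, length.out = 8),
              seq(0, dmax2, length.out = 8),
              name = "linear8")
}

#' Generate a curve pair for a consistency-condition scenario
#'
#' Scenarios correspond to the ways the Loewe Additivity Consistency
#' Condition can hold or break for Hill curves: `"lacc"` (curves differ
#' only in EC50, the condition holds), `"slopes"` (different slopes),
#' `"max_effect"` (different asymptotes), `"both"`.  In fixture mode
#' (`random = FALSE`) the canonical illustration parameter sets are
#' returned: the consistent pair has `y0 = 1`, `y_inf = 0`, `s = 2`,
#' `e1 = 1`, `e2 = 2`; the violation fixtures use `y0 = 1`, `e = 1`,
#' with `s1 = 1, s2 = 2` and/or `y_inf1 = 0.3, y_inf2 = 0` (other
#' parameters equal at `s = 1`, `y_inf = 0`).
#'
#' In randomized mode parameters are drawn from the current RNG stream:
#' `e` log-uniform on `[0.25, 4]`, `s` uniform on `[0.5, 4]`, `y_inf`
#' uniform on `[0, 0.4]`, with the scenario's equalities enforced by
#' sharing draws and its inequalities by a minimum margin (0.2 in `s`,
#' 0.1 in `y_inf`), achieved by rejection sampling.
#'
#' @param scenario one of `"lacc"`, `"slopes"`, `"max_effect"`, `"both"`.
#' @param random draw random parameters instead of the fixed fixtures.
#' @return A [curve_pair()].
#' @export
make_pair <- function(scenario = c("lacc", "slopes", "max_effect", "both"),
                      random = FALSE) {
  scenario <- match.arg(scenario)
  if (!random) {
    return(switch(scenario,
      lacc = curve_pair(hill_curve(1, 0, 1, 2), hill_curve(1, 0, 2, 2)),
      slopes = curve_pair(hill_curve(1, 0, 1, 1), hill_curve(1, 0, 1, 2)),
      max_effect = curve_pair(hill_curve(1, 0.3, 1, 1),
                              hill_curve(1, 0, 1, 1)),
      both = curve_pair(hill_curve(1, 0.3, 1, 1), hill_curve(1, 0, 1, 2))))
  }
  draw_e <- function() exp(stats::runif(1, log(0.25), log(4)))
  draw_s <- function() stats::runif(1, 0.5, 4)
  draw_yi <- function() stats::runif(1, 0, 0.4)
  draw_apart <- function(draw, margin) {
    repeat {
      a <- draw(); b <- draw()
      if (abs(a - b) >= margin) return(c(a, b))
    }
  }
  e1 <- draw_e(); e2 <- draw_e()
  if (scenario %in% c("slopes", "both")) {
    s <- draw_apart(draw_s, 0.2); s1 <- s[1]; s2 <- s[2]
  } else {
    s1 <- s2 <- draw_s()
  }
  if (scenario %in% c("max_effect", "both")) {
    yi <- draw_apart(draw_yi, 0.1); yi1 <- yi[1]; yi2 <- yi[2]
  } else {
    yi1 <- yi2 <- draw_yi()
  }
  curve_pair(hill_curve(1, yi1, e1, s1), hill_curve(1, yi2, e2, s2))
}

#' Simulate a checkerboard record
#'
#' Evaluates a null-model truth surface on the design grid and adds
#' i.i.d. Gaussian measurement noise.  Responses are not clipped to
#' `[0, 1]`, matching raw-viability readouts.  Deterministic given
#' `seed`; the generating model, parameters, noise level and seed are
#' stored as truth metadata.
#'
#' @param pair a [curve_pair()] (the generating conditional curves).
#' @param design a [dose_design()].
#' @param truth_kind surface kind used as ground truth (see
#'   [surface_model()]).
#' @param noise_sd standard deviation of the additive noise (response
#'   units), `>= 0`.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param id record identifier.
#' @return An object of class `"dr_record"`: list with `id`, `design`,
#'   `responses` (matrix, rows = doses1), `truth`.
#' @export
simulate_record <- function(pair, design, truth_kind = "gi", noise_sd = 0,
                            seed = NULL, id = "synthetic-record") {
  stopifnot(inherits(design, "dose_design"), noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  model <- surface_model(truth_kind, pair)
  m <- surface_matrix(model, design$doses1, design$doses2)
  if (noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = nrow(m))
  structure(list(id = id, design = design, responses = m,
                 truth = list(kind = truth_kind, pair = pair,
                              noise_sd = noise_sd, seed = seed)),
            class = "dr_record")
}

#' @export
print.dr_record <- function(x, ...) {
  cat(sprintf("Record '%s': %d x %d responses (design %s)\n", x$id,
              nrow(x$responses), ncol(x$responses), x$design$design_name))
  invisible(x)
}

#' Conditional series of a record
#'
#' Extracts the two single-compound series (the zero-dose column and row
#' of the checkerboard) as `dose`/`response` data frames, the input
#' expected by [fit_pair()].
#'
#' @param record a `"dr_record"`.
#' @return A list with elements `cond1` and `cond2`.
#' @export
conditional_series <- function(record) {
  d <- record$design
  list(cond1 = data.frame(dose = d$doses1, response = record$responses[, 1]),
       cond2 = data.frame(dose = d$doses2, response = record$responses[1, ]))
}

# Deterministic master-seed -> per-record seed derivation (documented
# splitting rule; keeps results below 2^31).
child_seed <- function(master, i) {
  as.integer((as.numeric(master) %% 2147483647 + 1664525 * as.numeric(i)) %%
               2147483647)
}

#' Simulate a population of records
#'
#' Draws `n_records` independent curve pairs for the given scenario (see
#' [make_pair()]), builds a per-record dose design, and simulates a
#' noisy checkerboard from the chosen truth surface.  Per-record seeds
#' are derived from the master seed by a fixed splitting rule, so the
#' population is reproducible as a whole and each record individually.
#'
#' The default design emulates per-compound dose ranging: an 8-dose
#' linear series from 0 to four times the compound's EC50 on each axis.
#' Pass `design_fun = function(pair) ...` to override (e.g. a fixed
#' [dilution6_design()]).
#'
#' @param n_records number of records, `>= 1`.
#' @param scenario passed to [make_pair()] (randomized mode).
#' @param truth_kind generating surface kind.
#' @param noise_sd measurement noise SD (response units).
#' @param seed master integer seed.
#' @param design_fun function from a [curve_pair()] to a
#'   [dose_design()].
#' @return A list of `"dr_record"` objects.
#' @export
simulate_population <- function(n_records, scenario = "both",
                                truth_kind = "gi", noise_sd = 0.02,
                                seed = 1,
                                design_fun = NULL) {
  stopifnot(n_records >= 1)
  if (is.null(design_fun))
    design_fun <- function(pair)
      linear8_design(4 * pair$curve1$e, 4 * pair$curve2$e)
  lapply(seq_len(n_records), function(i) {
    set.seed(child_seed(seed, i))
    pair <- make_pair(scenario, random = TRUE)
    simulate_record(pair, design_fun(pair), truth_kind = truth_kind,
                    noise_sd = noise_sd, seed = NULL,
                    id = sprintf("sim-%s-%03d", scenario, i))
  })
}
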