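#' Residuals of a null model against a measured record
#'
#' Evaluates the model on the record's dose grid and returns per-cell
#' residuals, oriented as predicted minus observed: a positive residual
#' means the model over-predicts the response (under-predicts the
#' effect).  All measured cells are used by default, including the
#' conditional (axis) cells; set `combination_only = TRUE` to drop
#' cells with a zero dose.  Missing cells are skipped.
#'
#' @param record a `"dr_record"` (see [simulate_record()],
#'   [read_record()]).
#' @param model a [surface_model()].
#' @param combination_only drop axis cells from the residual set.
#' @return A data frame with columns `dose_1`, `dose_2`, `observed`,
#'   `predicted`, `residual`.
#' @export
model_residuals <- function(record, model, combination_only = FALSE) {
  stopifnot(inherits(record, "dr_record"), inherits(model, "surface_model"))
  d <- record$design
  obs <- record$responses
  if (length(obs) == 0 || all(is.na(obs))) stop("record has no measurements")
  pred <- surface_matrix(model, d$doses1, d$doses2)
  g <- expand.grid(dose_1 = d$doses1, dose_2 = d$doses2)
  out <- data.frame(g, observed = as.vector(obs),
                    predicted = as.vector(pred))
  out$residual <- out$predicted - out$observed
  out <- out[is.finite(out$observed), , drop = FALSE]
  if (combination_only)
    out <- out[out$dose_1 > 0 & out$dose_2 > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bias and mean squared error of a null model on a record
#'
#' Summarizes the residuals \eqn{\hat y_i - y_i} of one model on one
#' record by their mean (bias) and mean square (mse):
#' \deqn{bias = \frac1N \sum_i (\hat y_i - y_i), \qquad
#'       mse = \frac1N \sum_i (\hat y_i - y_i)^2.}
#' An optional outlier rule excludes cells with
#' `|residual| > mad_mult * MAD` of the record's residuals under this
#' model before summarizing (off by default; the rule is this package's
#' own robustness choice and is mainly useful on real screens with
#' plate artifacts, not on clean synthetic data).
#'
#' @param record a `"dr_record"`.
#' @param model a [surface_model()].
#' @param mad_mult MAD multiplier of the outlier rule, or `NULL`
#'   (default) to disable exclusion.
#' @param combination_only see [model_residuals()].
#' @return A one-row data frame with columns `record_id`, `model_kind`,
#'   `bias`, `mse`, `n_points`, `n_outliers`.
#' @examples
#' p <- make_pair("both")
#' rec <- simulate_record(p, linear8_design(4, 4), "gi", 0.02, seed = 1)
#' evaluate_record(rec, surface_model("mean", p))
#' @export
evaluate_record <- function(record, model, mad_mult = NULL,
                            combination_only = FALSE) {
  res <- model_residuals(record, model, combination_only = combination_only)
  r <- res$residual
  n_out <- 0L
  if (!is.null(mad_mult)) {
    m <- stats::mad(r)
    keep <- if (m > 0) abs(r - stats::median(r)) <= mad_mult * m
            else rep(TRUE, length(r))
    n_out <- sum(!keep)
    r <- r[keep]
  }
  if (length(r) == 0L) stop("all residuals excluded as outliers")
  data.frame(record_id = record$id, model_kind = model$kind,
             bias = mean(r), mse = mean(r^2),
             n_points = length(r), n_outliers = n_out,
             stringsAsFactors = FALSE)
}

#' Compare the implicit and explicit mean models across records
#'
#' The end-to-end model-comparison pipeline: for each record, fit the
#' conditional series with a shared-`y0` Hill pair ([fit_pair()]), build
#' the two competing null surfaces from the fitted pair, and evaluate
#' bias and mse against the full measured checkerboard.  Records whose
#' fit is excluded (non-positive slope or EC50) or fails are dropped with
#' a recorded reason.  The per-record mse values of the two models are
#' then compared by a paired Wilcoxon signed-rank test; the default
#' one-sided alternative `"greater"` asks whether the first model's mse
#' is systematically larger than the second's (zeros dropped by the
#' signed-rank convention).
#'
#' @param records list of `"dr_record"` objects.
#' @param fits optional list of pre-computed [fit_pair()] results
#'   parallel to `records`; fitted on demand when `NULL`.
#' @param models character vector of two surface kinds to compare
#'   (default implicit `"gi"` vs explicit `"mean"`).
#' @param alternative alternative hypothesis for the paired test on mse,
#'   first model vs second (default `"greater"`).
#' @param solver a [solver_config()] for the implicit model.
#' @param mad_mult optional outlier rule, see [evaluate_record()].
#' @return A list of class `"model_comparison"`: `per_record` (data
#'   frame with record id and the bias/mse of both models), `p_mse`,
#'   `n`, `models`, `alternative`, `dropped` (named reasons), and
#'   `degenerate` (TRUE when all paired mse differences are zero, in
#'   which case `p_mse` is 1 by convention).
#' @export
compare_models <- function(records, fits = NULL, models = c("gi", "mean"),
                           alternative = "greater",
                           solver = solver_config(), mad_mult = NULL) {
  if (length(records) == 0L) stop("no records supplied")
  stopifnot(length(models) == 2L)
  if (is.null(fits))
    fits <- lapply(records, function(rec) {
      cs <- conditional_series(rec)
      tryCatch(fit_pair(cs$cond1, cs$cond2), error = function(e) e)
    })
  stopifnot(length(fits) == length(records))

  rows <- list(); dropped <- character()
  for (i in seq_along(records)) {
    f <- fits[[i]]
    id <- records[[i]]$id
    if (inherits(f, "error")) { dropped[id] <- conditionMessage(f); next }
    if (isTRUE(f$excluded)) { dropped[id] <- f$reason; next }
    ev <- tryCatch({
      e1 <- evaluate_record(records[[i]],
                            surface_model(models[1], f$pair, solver),
                            mad_mult = mad_mult)
      e2 <- evaluate_record(records[[i]],
                            surface_model(models[2], f$pair, solver),
                            mad_mult = mad_mult)
      data.frame(record_id = id,
                 bias_1 = e1$bias, bias_2 = e2$bias,
                 mse_1 = e1$mse, mse_2 = e2$mse,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(ev, "error")) { dropped[id] <- conditionMessage(ev); next }
    rows[[length(rows) + 1L]] <- ev
  }
  if (length(rows) == 0L) stop("no usable records after fitting")
  per_record <- do.call(rbind, rows)
  names(per_record) <- c("record_id",
                         paste0("bias_", models), paste0("mse_", models))
  d <- per_record[[paste0("mse_", models[1])]] -
       per_record[[paste0("mse_", models[2])]]
  degenerate <- all(d == 0)
  p_mse <- if (degenerate) 1 else suppressWarnings(
    stats::wilcox.test(per_record[[paste0("mse_", models[1])]],
                       per_record[[paste0("mse_", models[2])]],
                       paired = TRUE, alternative = alternative,
                       exact = FALSE))$p.value
  structure(list(per_record = per_record, p_mse = p_mse,
                 n = nrow(per_record), models = models,
                 alternative = alternative, dropped = dropped,
                 degenerate = degenerate),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison %s vs %s on %d records (%d dropped)\n",
              x$models[1], x$models[2], x$n, length(x$dropped)))
  cat(sprintf("  median mse: %s = %.4g, %s = %.4g\n",
              x$models[1], stats::median(x$per_record[[paste0("mse_", x$models[1])]]),
              x$models[2], stats::median(x$per_record[[paste0("mse_", x$models[2])]])))
  cat(sprintf("  paired Wilcoxon (mse %s '%s'): p = %.3g%s\n",
              x$models[1], x$alternative, x$p_mse,
              if (x$degenerate) " [degenerate: all differences zero]" else ""))
  invisible(x)
}
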