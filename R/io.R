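#' Read and write checkerboard records
#'
#' Two plain-text CSV dialects are supported.  `"long"` has columns
#' `dose_1, dose_2, response`, one measured cell per row; cells absent
#' from the file are marked missing.  `"matrix"` has the compound-2
#' doses as header row and the compound-1 doses as first column, with
#' the corner cell blank.  Doses are stored ascending (with 0 first)
#' regardless of file order.  Duplicate dose pairs and negative doses
#' are errors.
#'
#' @param path file path.
#' @param dialect `"long"` or `"matrix"`.
#' @param id record identifier (defaults to the file name).
#' @return `read_record()`: a `"dr_record"`.  `write_record()`: `path`,
#'   invisibly.
#' @export
read_record <- function(path, dialect = c("long", "matrix"), id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  if (dialect == "long") {
    df <- utils::read.csv(path)
    if (!all(c("dose_1", "dose_2", "response") %in% names(df)))
      stop("long dialect needs columns dose_1, dose_2, response")
    if (any(df$dose_1 < 0) || any(df$dose_2 < 0))
      stop("negative dose in ", path)
    if (anyDuplicated(df[c("dose_1", "dose_2")]))
      stop("duplicate dose pair in ", path)
    d1 <- sort(unique(df$dose_1)); d2 <- sort(unique(df$dose_2))
    m <- matrix(NA_real_, length(d1), length(d2))
    m[cbind(match(df$dose_1, d1), match(df$dose_2, d2))] <- df$response
  } else {
    raw <- utils::read.csv(path, header = FALSE,
                           colClasses = "character")
    if (nrow(raw) < 2 || ncol(raw) < 2) stop("matrix dialect too small")
    # empty strings in the body become NA (missing cells)
    num <- function(x) suppressWarnings(as.numeric(x))
    d2 <- num(unlist(raw[1, -1]))
    d1 <- num(raw[-1, 1])
    if (any(is.na(d1)) || any(is.na(d2)))
      stop("non-rectangular or unparseable matrix dialect in ", path)
    if (any(d1 < 0) || any(d2 < 0)) stop("negative dose in ", path)
    if (anyDuplicated(d1) || anyDuplicated(d2))
      stop("duplicate dose in ", path)
    m <- apply(as.matrix(raw[-1, -1, drop = FALSE]), c(1, 2), num)
    o1 <- order(d1); o2 <- order(d2)
    d1 <- d1[o1]; d2 <- d2[o2]
    m <- m[o1, o2, drop = FALSE]
  }
  design <- dose_design(d1, d2)
  dimnames(m) <- list(format(d1, trim = TRUE), format(d2, trim = TRUE))
  structure(list(id = id, design = design, responses = m, truth = NULL),
            class = "dr_record")
}

# fixed 9-significant-digit formatting for diff-stable CSV output
fmt_num <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[is.na(x)] <- ""
  out
}

#' @rdname read_record
#' @param record a `"dr_record"`.
#' @export
write_record <- function(record, path, dialect = c("long", "matrix")) {
  dialect <- match.arg(dialect)
  d <- record$design
  if (dialect == "long") {
    g <- expand.grid(dose_1 = d$doses1, dose_2 = d$doses2)
    df <- data.frame(dose_1 = fmt_num(g$dose_1), dose_2 = fmt_num(g$dose_2),
                     response = fmt_num(as.vector(record$responses)))
    df <- df[!is.na(as.vector(record$responses)), , drop = FALSE]
    df <- df[order(as.numeric(df$dose_1), as.numeric(df$dose_2)), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    header <- c("", fmt_num(d$doses2))
    body <- cbind(fmt_num(d$doses1),
                  matrix(fmt_num(record$responses), nrow = length(d$doses1)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = ","), con)
    writeLines(apply(body, 1, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read and write Hill parameter JSON
#'
#' A record parameter file holds one fitted Hill parameter set per
#' compound, `{"compound_1": {"y0":..., "y_inf":..., "e":..., "s":...},
#' "compound_2": {...}, "meta": {...}}`.
#'
#' @param path file path.
#' @return `read_pair_json()`: a [curve_pair()].  `write_pair_json()`:
#'   `path`, invisibly.
#' @export
read_pair_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("compound_1", "compound_2") %in% names(x)))
    stop("parameter JSON needs 'compound_1' and 'compound_2'")
  mk <- function(p) hill_curve(p$y0, p$y_inf, p$e, p$s)
  curve_pair(mk(x$compound_1), mk(x$compound_2))
}

#' @rdname read_pair_json
#' @param pair a [curve_pair()].
#' @param meta optional metadata list.
#' @export
write_pair_json <- function(pair, path, meta = NULL) {
  as_list <- function(crv) crv[c("y0", "y_inf", "e", "s")]
  x <- list(compound_1 = as_list(pair$curve1),
            compound_2 = as_list(pair$curve2))
  if (!is.null(meta)) x$meta <- meta
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Benchmark implicit vs explicit surface evaluation
#'
#' Times full-grid evaluation of the implicit General Isobole model and
#' the explicit mean model on the same design, `reps` times each, and
#' reports the median wall time per evaluation and their ratio
#' (implicit / explicit).  The ratio is hardware- and grid-dependent and
#' is reported for orientation, not asserted.
#'
#' @param pair a [curve_pair()].
#' @param design a [dose_design()].
#' @param reps number of repetitions (default 100).
#' @param solver a [solver_config()].
#' @return A list of class `"bench_report"` with `median_gi_s`,
#'   `median_mean_s`, `ratio`, `reps`, `grid_points`.
#' @export
bench_models <- function(pair, design, reps = 100,
                         solver = solver_config()) {
  stopifnot(reps >= 1)
  gi <- surface_model("gi", pair, solver)
  mn <- surface_model("mean", pair)
  # a single grid evaluation can be faster than the wall-clock resolution,
  # so each timed measurement is a calibrated block of evaluations whose
  # duration exceeds it, divided back to per-evaluation time
  block_of <- function(model) {
    t0 <- proc.time()[["elapsed"]]
    n <- 0L
    repeat {
      surface_matrix(model, design$doses1, design$doses2)
      n <- n + 1L
      if (proc.time()[["elapsed"]] - t0 > 0.02 || n >= 10000L) break
    }
    n
  }
  time_block <- function(model, n) {
    t0 <- proc.time()[["elapsed"]]
    for (i in seq_len(n)) surface_matrix(model, design$doses1, design$doses2)
    (proc.time()[["elapsed"]] - t0) / n
  }
  n_gi <- block_of(gi); n_mn <- block_of(mn)
  med_gi <- stats::median(vapply(seq_len(reps), function(i)
    time_block(gi, n_gi), 0))
  med_mn <- stats::median(vapply(seq_len(reps), function(i)
    time_block(mn, n_mn), 0))
  floor_s <- 1e-9   # last-resort guard against a zero denominator
  structure(list(median_gi_s = med_gi, median_mean_s = med_mn,
                 ratio = max(med_gi, floor_s) / max(med_mn, floor_s),
                 reps = reps,
                 grid_points = length(design$doses1) * length(design$doses2)),
            class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf(paste0("Benchmark (%d reps, %d grid points): implicit GI ",
                     "%.3g s, explicit mean %.3g s, ratio %.3g\n"),
              x$reps, x$grid_points, x$median_gi_s, x$median_mean_s,
              x$ratio))
  invisible(x)
}

#' Run configuration
#'
#' Bundles the knobs of a full pipeline run — solver settings, the
#' optional MAD outlier rule, default design and top doses, master seed
#' and verbosity — into one object that round-trips losslessly through
#' JSON, so an analysis can be rerun from its config file alone.
#'
#' @param solver a [solver_config()].
#' @param mad_mult MAD multiplier for outlier exclusion, or `NULL` for
#'   none (the default).
#' @param design default design name, `"linear8"` or `"dilution6"`.
#' @param dmax1,dmax2 default top doses per axis.
#' @param seed master integer seed.
#' @param verbose logical.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(solver = solver_config(), mad_mult = NULL,
                       design = c("linear8", "dilution6"),
                       dmax1 = 2.5, dmax2 = 2.5, seed = 1,
                       verbose = TRUE) {
  design <- match.arg(design)
  stopifnot(inherits(solver, "solver_config"))
  structure(list(solver = solver, mad_mult = mad_mult, design = design,
                 dmax1 = dmax1, dmax2 = dmax2,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$solver <- unclass(x$solver)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(solver = solver_config(x$solver$y_tol, x$solver$max_iter,
                                    x$solver$bracket_pad),
             mad_mult = x$mad_mult, design = x$design,
             dmax1 = x$dmax1, dmax2 = x$dmax2, seed = x$seed,
             verbose = x$verbose)
}
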