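#' Dynamical features of a single series
#'
#' Runs the full per-series pipeline: delay/dimension selection, RQA at the
#' adaptive threshold, and potential-landscape state counting. Degenerate
#' series (e.g. constant values) yield `NA` features rather than an error,
#' so cohort extraction can proceed subject by subject.
#'
#' @param series A [biomarker_series()] or numeric vector.
#' @param config An [rqa_config()].
#' @param max_lag,bins,max_dim Embedding-selection controls.
#' @param grid_size,floor_fraction Landscape controls.
#' @return One-row data frame: `n_states`, `det`, `mdl`, `ent`, `tau`, `m`,
#'   `epsilon`, `recurrence_rate`, `failed` (TRUE when the dynamics stage
#'   errored).
#' @export
series_features <- function(series, config = rqa_config(), max_lag = 25,
                            bins = 16, max_dim = 6, grid_size = 500,
                            floor_fraction = 0.05) {
  out <- data.frame(n_states = NA_integer_, det = NA_real_, mdl = NA_real_,
                    ent = NA_real_, tau = NA_integer_, m = NA_integer_,
                    epsilon = NA_real_, recurrence_rate = NA_real_,
                    failed = FALSE)
  res <- tryCatch({
    r <- suppressWarnings(
      rqa(series, config = config, max_lag = max_lag, bins = bins,
          max_dim = max_dim, keep_matrix = FALSE))
    ns <- count_states(series, grid_size, floor_fraction)
    list(r = r, ns = ns)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    out$failed <- TRUE
    return(out)
  }
  out$n_states <- res$ns
  out$det <- res$r$determinism
  out$mdl <- res$r$mean_diagonal_length
  out$ent <- res$r$entropy
  out$tau <- res$r$delay
  out$m <- res$r$dimension
  out$epsilon <- res$r$epsilon
  out$recurrence_rate <- res$r$recurrence_rate
  out
}

#' Extract the subject-by-feature table from a cohort
#'
#' One row per subject with the label, covariates, and, for each element,
#' the four dynamical features `<element>_n_states`, `<element>_det`,
#' `<element>_mdl`, `<element>_ent`. Per-series failures are recorded as
#' `NA` in the affected columns, never fatal.
#'
#' @param cohort A [simulate_cohort()] result (or the list produced by
#'   [read_cohort()]).
#' @param ... Passed to [series_features()].
#' @return A data frame (the feature table) with attribute `params`: a data
#'   frame of per-series embedding parameters (subject, element, tau, m,
#'   epsilon, recurrence rate, failure flag).
#' @export
extract_features <- function(cohort, ...) {
  stopifnot(length(cohort) > 0)
  elements <- attr(cohort, "elements")
  if (is.null(elements)) elements <- names(cohort[[1]]$series)
  rows <- vector("list", length(cohort))
  logs <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    row <- data.frame(subject_id = sub$subject_id, group = sub$group,
                      sex = sub$sex, age = sub$age,
                      stringsAsFactors = FALSE)
    lg <- list()
    for (el in elements) {
      f <- series_features(sub$series[[el]], ...)
      v <- f[, c("n_states", "det", "mdl", "ent")]
      names(v) <- paste0(el, "_", names(v))
      row <- cbind(row, v)
      lg[[el]] <- cbind(data.frame(subject_id = sub$subject_id, element = el,
                                   stringsAsFactors = FALSE),
                        f[, c("tau", "m", "epsilon", "recurrence_rate",
                              "failed")])
    }
    rows[[i]] <- row
    logs[[i]] <- do.call(rbind, lg)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  params <- do.call(rbind, logs)
  rownames(params) <- NULL
  structure(out, params = params, elements = elements)
}

#' Element labels of a feature table
#' @param table A feature table from [extract_features()].
#' @export
feature_elements <- function(table) {
  els <- attr(table, "elements")
  if (!is.null(els)) return(els)
  unique(sub("_n_states$", "", grep("_n_states$", names(table), value = TRUE)))
}
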