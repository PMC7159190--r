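#' @name pipeline
#' @title Configuration-driven pipeline orchestration
#'
#' @description
#' File plumbing tying the stages together: cohort specs and per-stage
#' parameters read from a YAML or JSON config, series written as one CSV per
#' subject-element with a cohort manifest, features/results/summaries as
#' CSV/JSON, and a provenance log (config hash, seeds, resolved parameters,
#' stage timings) for every run. A thin command-line wrapper around these
#' functions ships in `inst/cli/attractr.R`.
NULL

known_config_keys <- list(
  top = c("cohort", "manifest", "embedding", "rqa", "potential", "stats",
          "prediction", "output_dir", "seed", "plots"),
  cohort = c("preset", "n_cases", "n_controls", "generators", "sex_p",
             "age_mean", "age_sd", "length_range", "dt", "seed"),
  embedding = c("max_lag", "bins", "max_dim"),
  rqa = c("target_recurrence_rate", "lmin", "norm", "theiler_window"),
  potential = c("grid_size", "floor_fraction"),
  stats = c("fdr_scope"),
  prediction = c("train_fraction", "stratified", "classifiers", "n_boot",
                 "top_k", "seed")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
}

#' Read and validate a run configuration
#'
#' YAML or JSON (by extension). Unknown keys anywhere in the recognized
#' blocks are rejected.
#'
#' @param path Config file path.
#' @return A validated config list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(cfg, known_config_keys$top, "config")
  for (blk in c("cohort", "embedding", "rqa", "potential", "stats",
                "prediction")) {
    if (!is.null(cfg[[blk]])) {
      check_keys(cfg[[blk]], known_config_keys[[blk]], blk)
    }
  }
  cfg$config_path <- path
  class(cfg) <- "run_config"
  cfg
}

config_cohort_spec <- function(cfg) {
  cc <- cfg$cohort
  if (is.null(cc)) stop("config has no `cohort` block and no manifest")
  seed <- cc$seed %||% cfg$seed %||% 1
  if (!is.null(cc$preset)) {
    spec <- switch(cc$preset,
                   demo = demo_cohort_spec(seed = seed),
                   null = null_cohort_spec(seed = seed),
                   stop("unknown cohort preset: ", cc$preset))
    for (f in intersect(c("n_cases", "n_controls"), names(cc))) {
      spec[[f]] <- as.integer(cc[[f]])
    }
    return(spec)
  }
  cohort_spec(n_cases = cc$n_cases, n_controls = cc$n_controls,
              generators = cc$generators,
              sex_p = cc$sex_p %||% 0.5, age_mean = cc$age_mean %||% 55,
              age_sd = cc$age_sd %||% 10,
              length_range = cc$length_range %||% c(300, 600),
              dt = cc$dt %||% 1 / 48, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory: ", dir)
  }
  dir
}

## ---- cohort file I/O --------------------------------------------------------

#' Write a cohort to disk
#'
#' One CSV per subject-element (columns `time_years`, `value`) under
#' `dir/series/`, plus `dir/manifest.csv` with subject_id, group, sex, age,
#' element, path.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ensure_dir(file.path(dir, "series"))
  rows <- list()
  for (sub in cohort) {
    for (el in names(sub$series)) {
      rel <- file.path("series", paste0(sub$subject_id, "_", el, ".csv"))
      utils::write.csv(as.data.frame(sub$series[[el]]),
                       file.path(dir, rel), row.names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sub$subject_id, group = sub$group, sex = sub$sex,
        age = sub$age, element = el, path = rel, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a manifest written by [write_cohort()].
#' @return A `cohort` list as produced by [simulate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path)
  }
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(man) == 0) stop("manifest is empty")
  need <- c("subject_id", "group", "sex", "age", "element", "path")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  }
  base <- dirname(manifest_path)
  subjects <- lapply(split(man, man$subject_id), function(d) {
    series <- list()
    for (k in seq_len(nrow(d))) {
      f <- utils::read.csv(file.path(base, d$path[k]),
                           stringsAsFactors = FALSE)
      series[[d$element[k]]] <- biomarker_series(
        f$time_years, f$value, d$subject_id[k], d$element[k])
    }
    list(subject_id = d$subject_id[1], group = d$group[1], sex = d$sex[1],
         age = d$age[1], series = series)
  })
  subjects <- subjects[order(names(subjects))]
  structure(unname(subjects), class = "cohort",
            elements = unique(man$element))
}

## ---- stages -----------------------------------------------------------------

as_config <- function(config) {
  if (inherits(config, "run_config")) config else read_run_config(config)
}

stage_args <- function(cfg) {
  emb <- cfg$embedding %||% list()
  rq <- cfg$rqa %||% list()
  pot <- cfg$potential %||% list()
  list(config = rqa_config(
         target_recurrence_rate = rq$target_recurrence_rate %||% 0.10,
         lmin = rq$lmin %||% 3, norm = rq$norm %||% "euclidean",
         theiler_window = rq$theiler_window %||% 1),
       max_lag = emb$max_lag %||% 25, bins = emb$bins %||% 16,
       max_dim = emb$max_dim %||% 6,
       grid_size = pot$grid_size %||% 500,
       floor_fraction = pot$floor_fraction %||% 0.05)
}

#' Simulate a cohort from a config and write it to disk
#'
#' @param config A `run_config` or a path to one.
#' @return The manifest path, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- as_config(config)
  out <- ensure_dir(cfg$output_dir %||% ".")
  spec <- config_cohort_spec(cfg)
  message(sprintf(
    "simulating cohort: %d cases / %d controls, elements %s, seed %d",
    spec$n_cases, spec$n_controls, paste(spec$elements, collapse = ","),
    spec$seed))
  cohort <- simulate_cohort(spec)
  write_cohort(cohort, out)
}

#' Extract the feature table for a configured cohort
#'
#' Reads the cohort from `manifest` if given, otherwise simulates it from
#' the `cohort` block. Writes `features.csv` and the per-series
#' `embedding_params.csv` to the output directory.
#'
#' @param config A `run_config` or a path to one.
#' @return The feature table, invisibly.
#' @export
run_features <- function(config) {
  cfg <- as_config(config)
  out <- ensure_dir(cfg$output_dir %||% ".")
  cohort <- if (!is.null(cfg$manifest)) {
    read_cohort(cfg$manifest)
  } else if (file.exists(file.path(out, "manifest.csv"))) {
    read_cohort(file.path(out, "manifest.csv"))
  } else {
    simulate_cohort(config_cohort_spec(cfg))
  }
  args <- stage_args(cfg)
  table <- do.call(extract_features, c(list(cohort), args))
  utils::write.csv(table, file.path(out, "features.csv"), row.names = FALSE)
  utils::write.csv(attr(table, "params"),
                   file.path(out, "embedding_params.csv"), row.names = FALSE)
  if (isTRUE(cfg$plots)) write_cohort_plots(cohort, out, args)
  invisible(table)
}

write_cohort_plots <- function(cohort, out, args) {
  pdir <- ensure_dir(file.path(out, "plots"))
  for (sub in cohort[seq_len(min(4, length(cohort)))]) {
    for (el in names(sub$series)) {
      f <- file.path(pdir, paste0(sub$subject_id, "_", el, ".png"))
      grDevices::png(f, 900, 450)
      graphics::par(mfrow = c(1, 2))
      r <- tryCatch(rqa(sub$series[[el]], config = args$config),
                    error = function(e) NULL)
      if (!is.null(r)) plot(r)
      pl <- tryCatch(potential_landscape(sub$series[[el]]),
                     error = function(e) NULL)
      if (!is.null(pl)) plot(pl)
      grDevices::dev.off()
    }
  }
}

#' Group-comparison stage
#'
#' Runs all state-count and recurrence-feature tests with FDR adjustment
#' and writes `group_tests.csv`.
#'
#' @param config A `run_config` or a path to one.
#' @param table Optional feature table (recomputed otherwise).
#' @return The test-result data frame, invisibly.
#' @export
run_compare <- function(config, table = NULL) {
  cfg <- as_config(config)
  out <- ensure_dir(cfg$output_dir %||% ".")
  if (is.null(table)) table <- read_feature_table(out, cfg)
  res <- compare_groups(table,
                        fdr_scope = (cfg$stats %||% list())$fdr_scope
                          %||% "family")
  utils::write.csv(res, file.path(out, "group_tests.csv"), row.names = FALSE)
  invisible(res)
}

read_feature_table <- function(out, cfg) {
  fp <- file.path(out, "features.csv")
  if (file.exists(fp)) {
    utils::read.csv(fp, stringsAsFactors = FALSE)
  } else {
    run_features(cfg)
  }
}

#' Prediction stage
#'
#' Trains the configured classifiers, evaluates on the held-out split, and
#' writes `roc_points.csv`, `model_coefficients.csv`, and
#' `prediction_summary.json`.
#'
#' @param config A `run_config` or a path to one.
#' @param table Optional feature table.
#' @return The `attractor_prediction` object, invisibly.
#' @export
run_predict <- function(config, table = NULL) {
  cfg <- as_config(config)
  out <- ensure_dir(cfg$output_dir %||% ".")
  if (is.null(table)) table <- read_feature_table(out, cfg)
  pc <- cfg$prediction %||% list()
  pred <- classify_cohort(
    table,
    train_fraction = pc$train_fraction %||% 0.6,
    seed = pc$seed %||% cfg$seed %||% 1,
    stratified = pc$stratified %||% TRUE,
    classifiers = pc$classifiers %||% c("lasso", "gbt"),
    n_boot = pc$n_boot %||% 2000,
    top_k = pc$top_k %||% 5)
  roc_rows <- list(); coef_rows <- list(); summ <- list()
  for (cl in intersect(c("lasso", "gbt"), names(pred))) {
    r <- pred[[cl]]$roc
    roc_rows[[cl]] <- data.frame(classifier = cl, fpr = r$fpr, tpr = r$tpr)
    coefs <- if (cl == "lasso") {
      stats::setNames(pred[[cl]]$model$coefficients[, 1:2],
                      c("feature", "value"))
    } else {
      stats::setNames(pred[[cl]]$model$importance, c("feature", "value"))
    }
    coef_rows[[cl]] <- cbind(classifier = cl, coefs)
    summ[[cl]] <- list(auc = r$auc, auc_ci = r$auc_ci,
                       optimal_threshold = r$optimal_threshold,
                       accuracy = r$accuracy_at_threshold,
                       p_vs_chance = r$p_vs_chance,
                       top_k_auc = if (!is.null(pred[[cl]]$top_k))
                         pred[[cl]]$top_k$roc$auc else NULL)
  }
  utils::write.csv(do.call(rbind, roc_rows), file.path(out, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, coef_rows),
                   file.path(out, "model_coefficients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ, file.path(out, "prediction_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(pred)
}

#' Run the full pipeline
#'
#' simulate -> features -> compare -> predict, with a provenance log
#' (`run_log.json`: config hash, seeds, resolved parameters, per-stage
#' timings) written to the output directory.
#'
#' @param config A `run_config` or a path to one.
#' @return List with the feature table, test results, and prediction
#'   summary, invisibly.
#' @export
run_all <- function(config) {
  cfg <- as_config(config)
  out <- ensure_dir(cfg$output_dir %||% ".")
  timings <- c()
  tic <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    list(value = v, secs = proc.time()[["elapsed"]] - t0)
  }
  s1 <- tic(run_simulate(cfg)); timings["simulate"] <- s1$secs
  s2 <- tic(run_features(cfg)); timings["features"] <- s2$secs
  s3 <- tic(run_compare(cfg, s2$value)); timings["compare"] <- s3$secs
  s4 <- tic(run_predict(cfg, s2$value)); timings["predict"] <- s4$secs
  hash <- if (!is.null(cfg$config_path) && file.exists(cfg$config_path)) {
    unname(tools::md5sum(cfg$config_path))
  } else NA_character_
  log <- list(config_hash = hash, seed = cfg$seed %||% 1,
              parameters = stage_args(cfg)[c("max_lag", "bins", "max_dim",
                                             "grid_size", "floor_fraction")],
              rqa = unclass(stage_args(cfg)$config),
              timings_seconds = as.list(round(timings, 2)),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = s2$value, tests = s3$value,
                 prediction = s4$value))
}
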