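#' @name stats-module
#' @title Group comparisons of dynamical features
#'
#' @description
#' Case/control hypothesis tests on the per-subject features: Poisson
#' regression (log link) for quasi-stable state counts and ordinary linear
#' models for the recurrence features, both adjusted for sex and age (and a
#' smoking flag when the column is present), with Benjamini-Hochberg FDR
#' control across elements within each feature family.
NULL

covariate_terms <- function(table) {
  terms <- c("group", "sex", "age")
  if ("smoking" %in% names(table)) terms <- c(terms, "smoking")
  miss <- setdiff(c("group", "sex", "age"), names(table))
  if (length(miss)) {
    stop("feature table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  terms
}

test_result_row <- function(element, feature, fit, term = "groupcase",
                            flag = FALSE) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co) || any(!is.finite(co[term, ]))) {
    return(data.frame(element = element, feature = feature,
                      estimate = NA_real_, se = NA_real_, p_raw = NA_real_,
                      flag = TRUE, stringsAsFactors = FALSE))
  }
  data.frame(element = element, feature = feature,
             estimate = co[term, 1], se = co[term, 2],
             p_raw = co[term, 4], flag = flag, stringsAsFactors = FALSE)
}

#' Poisson model for quasi-stable state counts
#'
#' Log-linear Poisson regression of `<element>_n_states` on group + sex +
#' age (+ smoking when present), fit by IRLS; the group effect is a log rate
#' ratio with a Wald p-value. Non-convergence or separation is flagged in
#' the result, never raised.
#'
#' @param table Feature table from [extract_features()].
#' @param element Element label.
#' @return One-row data frame: element, feature, estimate (log rate ratio),
#'   se, p_raw, flag.
#' @export
fit_state_count_model <- function(table, element) {
  terms <- covariate_terms(table)
  ycol <- paste0(element, "_n_states")
  if (!ycol %in% names(table)) stop("no column ", ycol)
  d <- table[!is.na(table[[ycol]]), , drop = FALSE]
  d$group <- factor(d$group, levels = c("control", "case"))
  if (length(unique(d$group)) < 2 || min(table(d$group)) < 2) {
    stop("need at least 2 subjects in each group")
  }
  fml <- stats::as.formula(paste(ycol, "~", paste(terms, collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::poisson()),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) flagged <- TRUE
  test_result_row(element, "n_states", fit, flag = flagged)
}

#' Linear model for a recurrence feature
#'
#' OLS of the feature on group + sex + age (+ smoking when present); the
#' group effect carries a t-test p-value. Subjects with a missing feature
#' are dropped casewise; a constant feature yields a flagged degenerate
#' result.
#'
#' @inheritParams fit_state_count_model
#' @param feature One of "det", "mdl", "ent".
#' @export
fit_rqa_feature_model <- function(table, element,
                                  feature = c("det", "mdl", "ent")) {
  feature <- match.arg(feature)
  terms <- covariate_terms(table)
  ycol <- paste0(element, "_", feature)
  if (!ycol %in% names(table)) stop("no column ", ycol)
  d <- table[!is.na(table[[ycol]]), , drop = FALSE]
  d$group <- factor(d$group, levels = c("control", "case"))
  if (length(unique(d$group)) < 2 || min(table(d$group)) < 2) {
    stop("need at least 2 subjects with this feature in each group")
  }
  if (stats::sd(d[[ycol]]) == 0) {
    return(data.frame(element = element, feature = feature,
                      estimate = 0, se = NA_real_, p_raw = NA_real_,
                      flag = TRUE, stringsAsFactors = FALSE))
  }
  fml <- stats::as.formula(paste(ycol, "~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = d)
  test_result_row(element, feature, fit)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; monotone and order-preserving, never below the
#' raw p-values.
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' All group comparisons for a feature table
#'
#' State-count (Poisson) and recurrence-feature (linear) tests for every
#' element, with FDR adjustment applied within each feature family across
#' elements (default) or pooled over all tests.
#'
#' @param table Feature table from [extract_features()].
#' @param elements Element labels; autodetected by default.
#' @param fdr_scope "family" (adjust across elements within each of the
#'   n_states / det / mdl / ent families) or "all".
#' @return Data frame with one row per test: element, feature, estimate, se,
#'   p_raw, p_fdr, flag.
#' @export
compare_groups <- function(table, elements = NULL,
                           fdr_scope = c("family", "all")) {
  fdr_scope <- match.arg(fdr_scope)
  if (is.null(elements)) elements <- feature_elements(table)
  rows <- list()
  for (el in elements) {
    rows[[length(rows) + 1]] <- fit_state_count_model(table, el)
    for (f in c("det", "mdl", "ent")) {
      rows[[length(rows) + 1]] <- fit_rqa_feature_model(table, el, f)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  if (fdr_scope == "family") {
    for (f in unique(out$feature)) {
      idx <- out$feature == f
      out$p_fdr[idx] <- fdr_adjust(out$p_raw[idx])
    }
  } else {
    out$p_fdr <- fdr_adjust(out$p_raw)
  }
  rownames(out) <- NULL
  out
}
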