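#' @name prediction-module
#' @title Disease classification from dynamical features
#'
#' @description
#' Two classifiers over the dynamical features only (state counts and
#' recurrence features; the label and covariates never enter the design
#' matrix): an L1-penalized logistic regression (LASSO) and gradient-boosted
#' classification trees tuned by 3-fold cross-validation. Test-set scores
#' are summarized by an empirical ROC curve, its bootstrap confidence bands,
#' the threshold maximizing the distance from the chance diagonal, and a
#' rank-based test of the AUC against chance.
NULL

#' Design matrix of dynamical features
#'
#' Selects exactly the `<element>_{n_states,det,mdl,ent}` columns; the
#' label, identifiers, and covariates are excluded by schema.
#'
#' @param table Feature table.
#' @return Numeric matrix (subjects x features).
#' @export
feature_matrix <- function(table) {
  cols <- grep("_(n_states|det|mdl|ent)$", names(table), value = TRUE)
  if (length(cols) == 0) stop("no dynamical feature columns found")
  m <- as.matrix(table[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

class_labels <- function(table) {
  g <- as.character(table$group)
  bad <- setdiff(unique(g), c("case", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  as.integer(g == "case")
}

#' Train/test split
#'
#' Deterministic given the seed. The training set receives
#' floor(train_fraction * n) subjects (per class when stratified), the
#' remainder goes to the test set.
#'
#' @param table Feature table.
#' @param train_fraction Fraction of subjects used for training, in (0, 1);
#'   default 0.6.
#' @param seed Integer seed.
#' @param stratified Sample within each class (default TRUE).
#' @return List with `train` and `test` tables; errors if either side would
#'   miss a class.
#' @export
split_train_test <- function(table, train_fraction = 0.6, seed = 1,
                             stratified = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  y <- class_labels(table)
  if (length(unique(y)) < 2) stop("table contains a single class")
  n <- nrow(table)
  idx <- with_seed(seed, {
    if (stratified) {
      unlist(lapply(split(seq_len(n), y), function(ii) {
        sample(ii, floor(train_fraction * length(ii)))
      }), use.names = FALSE)
    } else {
      sample(seq_len(n), floor(train_fraction * n))
    }
  })
  train <- table[sort(idx), , drop = FALSE]
  test <- table[setdiff(seq_len(n), idx), , drop = FALSE]
  for (part in list(train, test)) {
    if (length(unique(class_labels(part))) < 2) {
      stop("split leaves a partition without both classes; ",
           "use stratified = TRUE or a different fraction")
    }
  }
  list(train = train, test = test)
}

## ---- LASSO ------------------------------------------------------------------

#' L1-penalized logistic classifier
#'
#' Features are standardized internally (glmnet's default). The penalty is
#' chosen by cross-validated binomial deviance on the training set unless a
#' `lambda` is supplied; the full path is retained in the fit. Features with
#' zero coefficient at the selected penalty are reported as excluded.
#'
#' @param train Training feature table.
#' @param seed Seed for the cross-validation folds.
#' @param nfolds CV folds for lambda selection (default 10).
#' @param lambda Optional fixed penalty; `NULL` selects by CV.
#' @return Object of class `attractor_lasso` with the glmnet fit, selected
#'   `lambda`, and a `coefficients` data frame (feature, estimate, selected).
#' @export
fit_lasso <- function(train, seed = 1, nfolds = 10, lambda = NULL) {
  x <- feature_matrix(train)
  y <- class_labels(train)
  if (length(unique(y)) < 2) stop("training data needs both classes")
  real_features <- colnames(x)
  if (ncol(x) < 2) {
    # glmnet requires >= 2 columns; pad with an inert constant
    x <- cbind(x, `.pad` = 0)
  }
  if (is.null(lambda)) {
    if (length(y) < 6) stop("too few training subjects (", length(y),
                            ") for cross-validated lambda selection; ",
                            "supply `lambda` explicitly")
    nfolds <- max(3L, min(nfolds, floor(length(y) / 3)))
    cv <- with_seed(seed, {
      foldid <- sample(rep_len(seq_len(nfolds), length(y)))
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                        foldid = foldid, standardize = TRUE)
    })
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
  } else {
    # include the requested lambda in a decreasing path for a stable fit
    path <- sort(unique(c(exp(seq(log(1), log(max(lambda, 1e-4)), length.out = 30)),
                          lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                          lambda = path, standardize = TRUE,
                          thresh = 1e-12)
    cv <- NULL
  }
  beta <- as.numeric(stats::coef(fit, s = lambda))[-1]
  keep <- colnames(x) %in% real_features
  coefs <- data.frame(feature = colnames(x)[keep], estimate = beta[keep],
                      selected = beta[keep] != 0, stringsAsFactors = FALSE)
  structure(list(fit = fit, cv = cv, lambda = lambda, coefficients = coefs,
                 features = real_features, padded = ncol(x) > sum(keep)),
            class = "attractor_lasso")
}

#' @export
predict.attractor_lasso <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)[, object$features, drop = FALSE]
  if (isTRUE(object$padded)) x <- cbind(x, `.pad` = 0)
  as.numeric(stats::predict(object$fit, newx = x, s = object$lambda,
                            type = "response"))
}

#' @export
print.attractor_lasso <- function(x, ...) {
  sel <- x$coefficients[x$coefficients$selected, ]
  cat(sprintf("<attractor_lasso> lambda = %.4g, %d/%d features selected\n",
              x$lambda, nrow(sel), nrow(x$coefficients)))
  if (nrow(sel)) print(sel, row.names = FALSE)
  invisible(x)
}

## ---- gradient boosting ------------------------------------------------------

#' Gradient-boosted tree classifier
#'
#' Boosted classification trees (logistic objective). Hyperparameters are
#' chosen by cross-validated AUC over a small declared grid (tree depth x
#' learning rate, boosting rounds by early stopping), 3 folds by default.
#'
#' @param train Training feature table.
#' @param seed Seed for fold assignment.
#' @param cv_folds Cross-validation folds (default 3).
#' @param grid Data frame of candidate `max_depth` / `eta` pairs.
#' @param max_rounds Cap on boosting rounds (default 150).
#' @return Object of class `attractor_gbt` with the booster, the winning
#'   hyperparameters, and an `importance` data frame (feature, gain).
#' @export
fit_gbt <- function(train, seed = 1, cv_folds = 3,
                    grid = expand.grid(max_depth = c(2, 3),
                                       eta = c(0.1, 0.3)),
                    max_rounds = 150) {
  x <- feature_matrix(train)
  y <- class_labels(train)
  if (nrow(x) < cv_folds) {
    stop("fewer training rows (", nrow(x), ") than cv_folds (", cv_folds, ")")
  }
  if (length(unique(y)) < 2) stop("training data needs both classes")
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    params <- list(objective = "binary:logistic", eval_metric = "auc",
                   max_depth = grid$max_depth[g], eta = grid$eta[g],
                   nthread = 1)
    cv <- with_seed(seed, {
      xgboost::xgb.cv(params = params, data = dtrain, nrounds = max_rounds,
                      nfold = cv_folds, early_stopping_rounds = 10,
                      verbose = 0, stratified = TRUE)
    })
    score <- max(cv$evaluation_log$test_auc_mean)
    it <- which.max(cv$evaluation_log$test_auc_mean)
    if (is.null(best) || score > best$score) {
      best <- list(score = score, params = params, nrounds = it)
    }
  }
  booster <- with_seed(seed, {
    xgboost::xgb.train(params = best$params, data = dtrain,
                       nrounds = best$nrounds, verbose = 0)
  })
  imp_raw <- tryCatch(
    xgboost::xgb.importance(model = booster),
    error = function(e) NULL)
  gain <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp_raw) && nrow(imp_raw)) {
    gain[imp_raw$Feature] <- imp_raw$Gain
  }
  importance <- data.frame(feature = names(gain), gain = as.numeric(gain),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$gain), ]
  rownames(importance) <- NULL
  structure(list(booster = booster, params = best$params,
                 nrounds = best$nrounds, cv_auc = best$score,
                 importance = importance, features = colnames(x)),
            class = "attractor_gbt")
}

#' @export
predict.attractor_gbt <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)[, object$features, drop = FALSE]
  as.numeric(stats::predict(object$booster, xgboost::xgb.DMatrix(x)))
}

#' @export
print.attractor_gbt <- function(x, ...) {
  cat(sprintf(
    "<attractor_gbt> depth %d, eta %.2f, %d rounds (cv AUC %.3f)\n",
    x$params$max_depth, x$params$eta, x$nrounds, x$cv_auc))
  print(utils::head(x$importance, 5), row.names = FALSE)
  invisible(x)
}

## ---- ROC machinery ----------------------------------------------------------

#' Empirical ROC curve and AUC
#'
#' Threshold sweep over the observed scores (classify positive when
#' score >= threshold). The AUC is computed by the trapezoid rule, which for
#' the empirical ROC equals the Mann-Whitney statistic
#' P(score_case > score_control) + 0.5 P(tie).
#'
#' @param scores Numeric classifier scores.
#' @param labels 0/1, logical, or "case"/"control" labels.
#' @return Object of class `roc_summary` with `fpr`, `tpr`, `thresholds`
#'   (decision boundaries, decreasing stringency), and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  u <- sort(unique(scores), decreasing = TRUE)
  # decision thresholds: above the largest score, then each observed score
  thr <- c(Inf, u)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  tpr <- fpr <- numeric(length(thr))
  for (k in seq_along(thr)) {
    pred <- scores >= thr[k]
    tpr[k] <- sum(pred & y == 1) / npos
    fpr[k] <- sum(pred & y == 0) / nneg
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc),
            class = "roc_summary")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "case")
  } else {
    as.integer(labels != 0)
  }
}

#' Mann-Whitney AUC (pairwise definition)
#'
#' @inheritParams roc_and_auc
#' @return P(case score > control score) + 0.5 P(tie).
#' @export
mann_whitney_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  r <- rank(scores)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Decision threshold maximizing distance from the chance diagonal
#'
#' Maximizes TPR - FPR (Youden's J, proportional to the perpendicular
#' distance from the diagonal) over cutpoints placed midway between adjacent
#' unique scores (and beyond the extremes); scores >= threshold are called
#' positive. Ties in J resolve to the lowest threshold.
#'
#' @param roc A `roc_summary`, or a list/vector of scores with `labels`.
#' @param scores,labels Alternative raw input.
#' @return The threshold value.
#' @export
optimal_threshold <- function(roc = NULL, scores = NULL, labels = NULL) {
  if (is.null(scores)) {
    if (!inherits(roc, "roc_summary") || is.null(roc$scores)) {
      stop("supply `scores` and `labels`, or a roc_summary carrying scores")
    }
    scores <- roc$scores; labels <- roc$labels
  }
  y <- as_binary_labels(labels)
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    mean(pred[y == 1]) - mean(pred[y == 0])
  }, numeric(1))
  cand[which(j == max(j))[1]]
}

accuracy_at_threshold <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  mean((scores >= threshold) == (y == 1))
}

#' Bootstrap ROC uncertainty
#'
#' Resamples (score, label) pairs with replacement `n_boot` times; each
#' resample yields an AUC (percentile 95% CI) and a sensitivity profile on a
#' fixed specificity grid (pointwise 95% band). Resamples missing a class
#' are redrawn.
#'
#' @inheritParams roc_and_auc
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param fpr_grid Fixed grid of false-positive rates for the band.
#' @return A `roc_summary` with additional fields `auc_ci` (length-2),
#'   `band` (data frame fpr/lo/hi), `boot_aucs`, `scores`, `labels`,
#'   `optimal_threshold`, `accuracy_at_threshold`, `p_vs_chance`, `n_boot`.
#' @export
bootstrap_roc <- function(scores, labels, n_boot = 2000, seed = 1,
                          fpr_grid = seq(0, 1, by = 0.02)) {
  y <- as_binary_labels(labels)
  point <- roc_and_auc(scores, y)
  tpr_at <- function(roc, grid) {
    vapply(grid, function(f) max(roc$tpr[roc$fpr <= f]), numeric(1))
  }
  aucs <- numeric(n_boot)
  band_mat <- matrix(NA_real_, n_boot, length(fpr_grid))
  n <- length(y)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2) break
      }
      rb <- roc_and_auc(scores[idx], y[idx])
      aucs[b] <- rb$auc
      band_mat[b, ] <- tpr_at(rb, fpr_grid)
    }
  })
  point$auc_ci <- unname(stats::quantile(aucs, c(0.025, 0.975)))
  point$band <- data.frame(
    fpr = fpr_grid,
    lo = apply(band_mat, 2, stats::quantile, 0.025),
    hi = apply(band_mat, 2, stats::quantile, 0.975))
  point$boot_aucs <- aucs
  point$scores <- scores
  point$labels <- y
  point$optimal_threshold <- optimal_threshold(scores = scores, labels = y)
  point$accuracy_at_threshold <-
    accuracy_at_threshold(scores, y, point$optimal_threshold)
  point$p_vs_chance <- auc_rank_test(scores, y)
  point$n_boot <- n_boot
  point
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> AUC = %.3f", x$auc))
  if (!is.null(x$auc_ci)) {
    cat(sprintf(" (%.2f-%.2f, %d bootstraps)", x$auc_ci[1], x$auc_ci[2],
                x$n_boot))
  }
  cat("\n")
  if (!is.null(x$optimal_threshold)) {
    cat(sprintf("  threshold %.3f -> accuracy %.1f%%; p vs chance = %.4g\n",
                x$optimal_threshold, 100 * x$accuracy_at_threshold,
                x$p_vs_chance))
  }
  invisible(x)
}

#' @export
plot.roc_summary <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  if (!is.null(x$band)) {
    graphics::polygon(c(x$band$fpr, rev(x$band$fpr)),
                      c(x$band$lo, rev(x$band$hi)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x$fpr, x$tpr, type = "s")
  }
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Rank-based test of the AUC against chance
#'
#' One-sided Mann-Whitney (Wilcoxon rank-sum) test that case scores
#' stochastically dominate control scores, i.e. AUC > 0.5: exact for small
#' samples without ties, normal approximation with tie correction otherwise.
#' Fully tied scores give the boundary value p = 0.5.
#'
#' @inheritParams roc_and_auc
#' @return One-sided p-value.
#' @export
auc_rank_test <- function(scores, labels) {
  y <- as_binary_labels(labels)
  cases <- scores[y == 1]; controls <- scores[y == 0]
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both classes required")
  }
  if (diff(range(scores)) == 0) return(0.5)
  suppressWarnings(
    stats::wilcox.test(cases, controls, alternative = "greater",
                       exact = (length(scores) <= 50 &&
                                  !any(duplicated(scores))))$p.value)
}

## ---- refit on top features --------------------------------------------------

top_features <- function(model, k) {
  ranked <- switch(
    class(model)[1],
    attractor_lasso = {
      co <- model$coefficients
      co$feature[order(-abs(co$estimate))]
    },
    attractor_gbt = model$importance$feature,
    stop("unsupported model class: ", class(model)[1]))
  if (k > length(ranked)) {
    stop("k = ", k, " exceeds the number of features (", length(ranked), ")")
  }
  ranked[seq_len(k)]
}

subset_features <- function(table, features) {
  keep <- c(intersect(c("subject_id", "group", "sex", "age", "smoking"),
                      names(table)), features)
  table[, keep, drop = FALSE]
}

#' Refit a classifier on its top-k features
#'
#' Re-trains the same classifier family on the k features with the largest
#' absolute coefficient (LASSO) or importance (boosted trees), then
#' evaluates on the untouched test set.
#'
#' @param model A fitted `attractor_lasso` or `attractor_gbt`.
#' @param train,test Feature tables used for the original fit.
#' @param k Number of features retained (default 5).
#' @param seed Seed passed to the refit.
#' @param n_boot Bootstrap replicates for the refit ROC.
#' @return List with `features`, `model`, `roc` (a bootstrap `roc_summary`
#'   on the test set).
#' @export
top_k_refit <- function(model, train, test, k = 5, seed = 1, n_boot = 2000) {
  feats <- top_features(model, k)
  tr <- subset_features(train, feats)
  te <- subset_features(test, feats)
  refit <- if (inherits(model, "attractor_lasso")) {
    fit_lasso(tr, seed = seed)
  } else {
    fit_gbt(tr, seed = seed)
  }
  scores <- stats::predict(refit, te)
  list(features = feats, model = refit,
       roc = bootstrap_roc(scores, class_labels(te), n_boot = n_boot,
                           seed = seed))
}

## ---- orchestration ----------------------------------------------------------

#' Train and evaluate both classifiers on a feature table
#'
#' Splits the table, fits the requested classifiers on the training part,
#' scores the held-out part, and summarizes each with a bootstrap ROC,
#' optimal threshold and accuracy, rank test against chance, and a top-k
#' refit.
#'
#' @param table Feature table from [extract_features()].
#' @param train_fraction,seed,stratified Split controls
#'   (see [split_train_test()]).
#' @param classifiers Subset of c("lasso", "gbt").
#' @param n_boot Bootstrap replicates (default 2000).
#' @param top_k Features kept in the refit (default 5); set 0 to skip.
#' @return Object of class `attractor_prediction`: per-classifier list with
#'   `model`, `scores`, `roc`, `top_k`; plus the split sizes.
#' @export
classify_cohort <- function(table, train_fraction = 0.6, seed = 1,
                            stratified = TRUE,
                            classifiers = c("lasso", "gbt"), n_boot = 2000,
                            top_k = 5) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  sp <- split_train_test(table, train_fraction, seed, stratified)
  out <- list(n_train = nrow(sp$train), n_test = nrow(sp$test),
              train_fraction = train_fraction, seed = seed)
  for (cl in classifiers) {
    model <- if (cl == "lasso") fit_lasso(sp$train, seed = seed)
             else fit_gbt(sp$train, seed = seed)
    scores <- stats::predict(model, sp$test)
    roc <- bootstrap_roc(scores, class_labels(sp$test), n_boot = n_boot,
                         seed = seed)
    res <- list(model = model, scores = scores, roc = roc)
    if (top_k > 0 && top_k <= ncol(feature_matrix(table))) {
      res$top_k <- top_k_refit(model, sp$train, sp$test, k = top_k,
                               seed = seed, n_boot = n_boot)
    }
    out[[cl]] <- res
  }
  structure(out, class = "attractor_prediction")
}

#' @export
print.attractor_prediction <- function(x, ...) {
  cat(sprintf("<attractor_prediction> train %d / test %d\n",
              x$n_train, x$n_test))
  for (cl in intersect(c("lasso", "gbt"), names(x))) {
    r <- x[[cl]]$roc
    cat(sprintf("  %-5s AUC %.3f (%.2f-%.2f)  acc %.1f%% @ %.3f  p = %.4g\n",
                cl, r$auc, r$auc_ci[1], r$auc_ci[2],
                100 * r$accuracy_at_threshold, r$optimal_threshold,
                r$p_vs_chance))
    if (!is.null(x[[cl]]$top_k)) {
      cat(sprintf("        top-%d refit AUC %.3f (%.2f-%.2f)\n",
                  length(x[[cl]]$top_k$features), x[[cl]]$top_k$roc$auc,
                  x[[cl]]$top_k$roc$auc_ci[1], x[[cl]]$top_k$roc$auc_ci[2]))
    }
  }
  invisible(x)
}
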