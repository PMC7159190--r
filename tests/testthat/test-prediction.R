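# Table-level fixtures: features with a controllable amount of signal.
pred_table <- function(n_case = 36, n_control = 31, seed = 1, signal = 1,
                       p_noise = 6) {
  set.seed(seed)
  n <- n_case + n_control
  grp <- rep(c("case", "control"), c(n_case, n_control))
  tab <- data.frame(subject_id = sprintf("P%02d", 1:n), group = grp,
                    sex = rbinom(n, 1, 0.5), age = rnorm(n, 55, 10),
                    stringsAsFactors = FALSE)
  tab$Cu_det <- rnorm(n) + signal * (grp == "case")
  for (k in seq_len(p_noise)) {
    tab[[paste0("El", k, "_ent")]] <- rnorm(n)
  }
  tab
}

test_that("feature matrix excludes label, identifiers, and covariates", {
  tab <- pred_table()
  m <- feature_matrix(tab)
  expect_false(any(c("group", "subject_id", "sex", "age") %in% colnames(m)))
  expect_true(all(grepl("_(n_states|det|mdl|ent)$", colnames(m))))
  expect_error(feature_matrix(tab[, 1:4]), "no dynamical feature")
})

test_that("train/test split follows the floor rounding rule", {
  tab <- pred_table()
  sp <- split_train_test(tab, 0.6, seed = 2, stratified = FALSE)
  expect_equal(nrow(sp$train), 40)   # floor(0.6 * 67)
  expect_equal(nrow(sp$test), 27)
  expect_setequal(c(sp$train$subject_id, sp$test$subject_id),
                  tab$subject_id)
  # deterministic given seed
  sp2 <- split_train_test(tab, 0.6, seed = 2, stratified = FALSE)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  # tiny balanced stratified split keeps one of each class per side
  tab4 <- pred_table(2, 2)
  sp4 <- split_train_test(tab4, 0.5, seed = 1, stratified = TRUE)
  expect_equal(sort(sp4$train$group), c("case", "control"))
  expect_equal(sort(sp4$test$group), c("case", "control"))
  # single-class input is rejected
  expect_error(split_train_test(tab[tab$group == "case", ], 0.5, 1),
               "single class")
  expect_error(split_train_test(tab, 0), "train_fraction")
})

test_that("lasso path admits a separating feature first", {
  set.seed(3)
  tab <- pred_table(20, 20, signal = 50, p_noise = 5)  # near-separating
  fit <- fit_lasso(tab, seed = 1)
  beta <- fit$fit$beta
  first_entry <- apply(as.matrix(beta) != 0, 1, function(r) {
    w <- which(r); if (length(w)) min(w) else Inf
  })
  expect_equal(names(which.min(first_entry)), "Cu_det")
  expect_true(fit$coefficients$selected[fit$coefficients$feature == "Cu_det"])
})

test_that("heavy penalty with pure-noise features gives an intercept-only model", {
  tab <- pred_table(signal = 0)
  fit <- fit_lasso(tab, lambda = 5)
  expect_true(all(fit$coefficients$estimate == 0))
})

test_that("unpenalized lasso limit matches the logistic MLE", {
  set.seed(4)
  n <- 400
  tab <- data.frame(subject_id = as.character(1:n),
                    group = rep(c("case", "control"), each = n / 2),
                    sex = rbinom(n, 1, 0.5), age = rnorm(n, 50, 8))
  tab$A_det <- rnorm(n) + 0.8 * (tab$group == "case")
  tab$B_ent <- rnorm(n) - 0.5 * (tab$group == "case")
  fit0 <- fit_lasso(tab, lambda = 0)
  ref <- glm(I(group == "case") ~ A_det + B_ent, data = tab,
             family = binomial())
  expect_equal(fit0$coefficients$estimate,
               unname(coef(ref)[c("A_det", "B_ent")]), tolerance = 1e-4)
})

test_that("boosted trees rank a monotone signal feature on top", {
  tab <- pred_table(30, 30, seed = 5, signal = 2)
  fit <- fit_gbt(tab, seed = 1)
  expect_equal(fit$importance$feature[1], "Cu_det")
  expect_gt(fit$importance$gain[1], 0.5)
  expect_error(fit_gbt(pred_table(1, 1), cv_folds = 3), "cv_folds")
})

test_that("boosted trees on pure noise stay near chance on held-out data", {
  aucs <- vapply(1:4, function(s) {
    tab <- pred_table(34, 33, seed = s + 10, signal = 0)
    sp <- split_train_test(tab, 0.6, seed = s)
    fit <- fit_gbt(sp$train, seed = s)
    roc_and_auc(predict(fit, sp$test), class_labels_for_test(sp$test))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("ROC/AUC equals the pairwise Mann-Whitney statistic", {
  r <- roc_and_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_and_auc(c(1, 2, 3, 10, 11, 12),
                           c(0, 0, 0, 1, 1, 1))$auc, 1.0)
  set.seed(6)
  for (k in 1:15) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    r <- roc_and_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    expect_equal(r$auc, mann_whitney_auc(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  }
})

test_that("optimal threshold maximizes distance from the diagonal", {
  # perfect classifier: midpoint of the separating gap
  th <- optimal_threshold(scores = c(0.1, 0.2, 0.7, 0.9),
                          labels = c(0, 0, 1, 1))
  expect_equal(th, 0.45)
  # two tied candidates resolve to the lower threshold
  th2 <- optimal_threshold(scores = c(0.2, 0.8), labels = c(0, 1))
  expect_equal(th2, 0.5)
  # matches exhaustive search on a noisy ROC
  set.seed(7)
  scores <- runif(40); labels <- rbinom(40, 1, plogis(3 * (scores - 0.5)))
  if (length(unique(labels)) == 2) {
    th3 <- optimal_threshold(scores = scores, labels = labels)
    grid <- sort(unique(c(scores - 1e-9, scores + 1e-9)))
    j <- vapply(grid, function(t) {
      mean(scores[labels == 1] >= t) - mean(scores[labels == 0] >= t)
    }, numeric(1))
    jth <- mean(scores[labels == 1] >= th3) -
      mean(scores[labels == 0] >= th3)
    expect_equal(jth, max(j), tolerance = 1e-12)
  }
})

test_that("bootstrap ROC handles degenerate and perfect classifiers", {
  expect_equal(bootstrap_roc(rep(0.5, 20), rep(c(0, 1), 10), n_boot = 50,
                             seed = 1)$auc_ci, c(0.5, 0.5))
  bp <- bootstrap_roc(c(1:10 / 100, 0.9 + 1:10 / 100), rep(c(0, 1), each = 10),
                      n_boot = 50, seed = 1)
  expect_equal(bp$auc_ci, c(1, 1))
  expect_equal(bp$auc, 1)
})

test_that("bootstrap interval brackets the point AUC", {
  set.seed(8)
  inside <- vapply(1:25, function(s) {
    scores <- rnorm(40); labels <- rbinom(40, 1, plogis(scores))
    if (length(unique(labels)) < 2) return(TRUE)
    b <- bootstrap_roc(scores, labels, n_boot = 300, seed = s)
    b$auc >= b$auc_ci[1] && b$auc <= b$auc_ci[2]
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("rank test is exact under separation and calibrated under the null", {
  p <- auc_rank_test(c(rnorm(10, 10), rnorm(10)), rep(c(1, 0), each = 10))
  expect_lt(p, 1e-4)
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-10)
  expect_equal(auc_rank_test(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(9)
  pnull <- replicate(300, {
    y <- c(rep(0, 15), rep(1, 15))
    auc_rank_test(rnorm(30), y)
  })
  expect_gt(suppressWarnings(ks.test(pnull, "punif"))$p.value, 0.001)
})

test_that("top-k refit reproduces the full model at k = all features", {
  tab <- pred_table(24, 24, seed = 10, signal = 1.5, p_noise = 3)
  sp <- split_train_test(tab, 0.6, seed = 1)
  fit <- fit_lasso(sp$train, seed = 1)
  k_all <- ncol(feature_matrix(tab))
  re <- top_k_refit(fit, sp$train, sp$test, k = k_all, seed = 1, n_boot = 50)
  expect_equal(re$roc$auc,
               roc_and_auc(predict(fit, sp$test),
                           class_labels_for_test(sp$test))$auc)
  expect_error(top_k_refit(fit, sp$train, sp$test, k = k_all + 1),
               "exceeds")
  # single informative feature: k = 1 performs like the full model
  re1 <- top_k_refit(fit, sp$train, sp$test, k = 1, seed = 1, n_boot = 50)
  expect_equal(re1$features, "Cu_det")
  expect_gt(re1$roc$auc, re$roc$auc - 0.1)
})

test_that("classify_cohort summarizes both classifiers", {
  tab <- pred_table(26, 26, seed = 11, signal = 2, p_noise = 2)
  pred <- classify_cohort(tab, seed = 3, n_boot = 100, top_k = 2)
  for (cl in c("lasso", "gbt")) {
    r <- pred[[cl]]$roc
    expect_true(r$auc >= r$auc_ci[1] && r$auc <= r$auc_ci[2])
    expect_true(r$auc > 0.5)
    expect_length(pred[[cl]]$top_k$features, 2)
  }
  lasso_only <- classify_cohort(tab, seed = 3, classifiers = "lasso",
                                n_boot = 50, top_k = 0)
  expect_null(lasso_only$gbt)
})
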