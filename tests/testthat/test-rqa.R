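test_that("adaptive epsilon is the target quantile of the distance set", {
  set.seed(1)
  # 100 points in 1-D with almost surely distinct pairwise distances
  traj <- takens_embed(rnorm(100), 1, 1)
  eps <- adaptive_epsilon(traj, rqa_config(0.10))
  d <- as.matrix(dist(traj$points))
  dv <- sort(d[upper.tri(d)])
  expect_equal(as.numeric(eps), dv[floor(0.10 * length(dv))])  # 495th of 4950
  expect_equal(attr(eps, "realized_rate"), 0.1, tolerance = 1e-6)
  # target 1: threshold reaches the maximum distance, rate 1
  eps1 <- adaptive_epsilon(traj, rqa_config(1.0))
  expect_gte(as.numeric(eps1), max(dv))
  expect_equal(attr(eps1, "realized_rate"), 1)
})

test_that("adaptive epsilon rejects degenerate geometry", {
  traj <- takens_embed(rep(3, 30), 1, 2)
  expect_error(adaptive_epsilon(traj), "degenerate geometry")
})

test_that("realized rate at the computed threshold matches brute force", {
  set.seed(2)
  x <- rnorm(200)
  traj <- takens_embed(x, 1, 3)
  eps <- adaptive_epsilon(traj, rqa_config(0.10))
  D <- brute_distmat(traj$points)
  n <- nrow(D); hits <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (D[i, j] <= eps) hits <- hits + 1
  }
  expect_equal(hits / tot, 0.10, tolerance = 0.005)
})

test_that("recurrence matrix structure follows the threshold geometry", {
  # a single repeated point: everything off-Theiler recurs
  traj <- list(points = matrix(1, 20, 2), delay = 1L, dim = 2L)
  class(traj) <- "embedded_trajectory"
  rm1 <- recurrence_matrix(traj, 0.5, rqa_config())
  expect_true(all(rm1$matrix[abs(row(rm1$matrix) - col(rm1$matrix)) >= 1]))
  expect_false(any(diag(rm1$matrix)))
  expect_equal(rm1$recurrence_rate, 1)
  # two clusters farther apart than epsilon: block structure
  pts <- rbind(matrix(rnorm(20, 0, 0.01), 10, 2),
               matrix(rnorm(20, 10, 0.01), 10, 2))
  traj2 <- structure(list(points = pts, delay = 1L, dim = 2L),
                     class = "embedded_trajectory")
  rm2 <- recurrence_matrix(traj2, 1, rqa_config())
  expect_false(any(rm2$matrix[1:10, 11:20]))
  expect_true(all(rm2$matrix[1:5, 6:10]))
})

test_that("recurrence matrix and histogram match brute force exactly", {
  set.seed(3)
  for (k in 1:12) {
    n <- sample(20:90, 1)
    x <- cumsum(rnorm(n))
    tau <- sample(1:3, 1); m <- sample(1:3, 1)
    tw <- sample(0:2, 1)
    cfg <- rqa_config(0.15, theiler_window = tw)
    traj <- takens_embed(x, tau, m)
    D <- brute_distmat(brute_embed(x, tau, m))
    eps <- brute_epsilon(D, 0.15, tw)
    expect_equal(as.numeric(adaptive_epsilon(traj, cfg)), eps)
    R <- recurrence_matrix(traj, eps, cfg)
    expect_identical(unname(R$matrix), brute_recmat(D, eps, tw))
    P <- diagonal_histogram(R$matrix, tw)
    Pb <- brute_diag_hist(R$matrix, tw)
    expect_identical(as.integer(P), as.integer(Pb))
    expect_identical(names(P), names(Pb))
  }
})

test_that("diagonal histogram worked examples", {
  allones <- matrix(TRUE, 5, 5)
  P <- diagonal_histogram(allones, 1)
  expect_equal(P, setNames(rep(1L, 4), 1:4))
  ident <- diag(5) == 1
  expect_length(diagonal_histogram(ident, 1), 0)
})

test_that("feature formulas reproduce hand arithmetic exactly", {
  P1 <- setNames(1, "5")
  expect_equal(determinism(P1, 3), 1.0)
  P2 <- setNames(c(4, 3), c("1", "2"))
  expect_equal(determinism(P2, 3), 0.0)
  P3 <- setNames(c(4, 2), c("1", "3"))
  expect_equal(determinism(P3, 3), 0.6, tolerance = 1e-12)
  P4 <- setNames(c(2, 1), c("3", "5"))
  expect_equal(mean_diagonal_length(P4, 3), 11 / 3, tolerance = 1e-12)
  expect_equal(mean_diagonal_length(setNames(7, "4"), 3), 4)
  expect_true(is.na(mean_diagonal_length(P2, 3)))   # no line reaches lmin
  expect_equal(diagonal_entropy(setNames(9, "6"), 3), 0)
  expect_equal(diagonal_entropy(setNames(c(2, 2), c("3", "7")), 3), log(2),
               tolerance = 1e-12)
  P5 <- setNames(c(1, 1, 2), c("3", "4", "5"))
  expect_equal(diagonal_entropy(P5, 3),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-12)
  # empty histogram: missing-value marker, never zero
  empty <- setNames(integer(0), character(0))
  expect_true(is.na(determinism(empty, 3)))
  expect_true(is.na(diagonal_entropy(empty, 3)))
})

test_that("end-to-end pipeline agrees with the brute-force reference", {
  set.seed(4)
  for (k in 1:3) {
    n <- sample(80:150, 1)
    x <- sin(2 * pi * (0:(n - 1)) / 17.3) + rnorm(n, 0, 0.2)
    r <- rqa(x, delay = 3, dimension = 2)
    D <- brute_distmat(brute_embed(x, 3, 2))
    eps <- brute_epsilon(D, 0.10, 1)
    R <- brute_recmat(D, eps, 1)
    P <- brute_diag_hist(R, 1)
    f <- brute_rqa_features(P, 3)
    expect_equal(r$epsilon, eps)
    expect_identical(unname(r$matrix), R)
    expect_equal(r$determinism, f$det, tolerance = 1e-12)
    expect_equal(r$mean_diagonal_length, f$mdl, tolerance = 1e-12)
    expect_equal(r$entropy, f$ent, tolerance = 1e-12)
  }
})

test_that("periodic signals score higher determinism than noise", {
  x <- make_sine(500, 40.3)
  rs <- suppressWarnings(rqa(x))
  expect_gte(rs$determinism, 0.95)
  set.seed(5)
  rw <- suppressWarnings(rqa(rnorm(500)))
  expect_lt(rw$determinism, rs$determinism)
  expect_error(suppressWarnings(rqa(rep(1, 100))), "degenerate|constant")
})

test_that("realized rate stays within half a percentage point of target", {
  set.seed(6)
  for (k in 1:8) {
    x <- cumsum(rnorm(sample(100:300, 1)))
    r <- suppressWarnings(rqa(x))
    expect_lt(abs(r$recurrence_rate - 0.10), 0.005)
    expect_true(r$determinism >= 0 && r$determinism <= 1)
    if (!is.na(r$mean_diagonal_length)) {
      expect_gte(r$mean_diagonal_length, r$config$lmin)
    }
    if (!is.na(r$entropy)) expect_gte(r$entropy, 0)
  }
})

test_that("features are invariant to affine rescaling of the values", {
  set.seed(7)
  x <- cumsum(rnorm(250))
  r1 <- suppressWarnings(rqa(x, delay = 2, dimension = 3))
  r2 <- suppressWarnings(rqa(5 * x - 40, delay = 2, dimension = 3))
  expect_equal(r1$determinism, r2$determinism, tolerance = 1e-12)
  expect_equal(r1$mean_diagonal_length, r2$mean_diagonal_length,
               tolerance = 1e-12)
  expect_equal(r1$entropy, r2$entropy, tolerance = 1e-12)
  expect_equal(r2$epsilon, 5 * r1$epsilon, tolerance = 1e-10)
})

test_that("maximum-norm configuration is honoured", {
  set.seed(8)
  x <- cumsum(rnorm(60))
  cfg <- rqa_config(norm = "maximum", target_recurrence_rate = 0.2)
  traj <- takens_embed(x, 1, 3)
  eps <- adaptive_epsilon(traj, cfg)
  D <- brute_distmat(traj$points, norm = "maximum")
  expect_equal(as.numeric(eps), brute_epsilon(D, 0.2, 1))
})
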