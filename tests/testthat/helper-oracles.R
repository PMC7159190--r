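# Independent brute-force reference implementations used as oracles.
# Deliberately written as plain double loops / direct formula transcriptions,
# sharing no code with the package internals.

# Euclidean distance between embedding rows i and j, computed by loop.
brute_embed <- function(x, tau, m) {
  n <- length(x) - (m - 1) * tau
  pts <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (k in seq_len(m)) pts[i, k] <- x[i + (k - 1) * tau]
  }
  pts
}

brute_distmat <- function(pts, norm = "euclidean") {
  n <- nrow(pts)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- pts[i, ] - pts[j, ]
      if (norm == "maximum") {
        D[i, j] <- max(abs(d))
      } else {
        s <- 0                     # plain double accumulation
        for (q in d) s <- s + q * q
        D[i, j] <- sqrt(s)
      }
    }
  }
  D
}

# epsilon as the k-th smallest off-Theiler distance, k = floor(rate * N)
brute_epsilon <- function(D, target, theiler = 1) {
  n <- nrow(D)
  vals <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i >= max(1, theiler)) vals <- c(vals, D[i, j])
    }
  }
  if (theiler == 0) vals <- c(vals, rep(0, n))
  sort(vals)[max(1, floor(target * length(vals)))]
}

brute_recmat <- function(D, eps, theiler = 1) {
  n <- nrow(D)
  R <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) >= theiler && D[i, j] <= eps) R[i, j] <- TRUE
    }
  }
  R
}

# diagonal line histogram by explicit run scanning, upper triangle
brute_diag_hist <- function(R, theiler = 1) {
  n <- nrow(R)
  lens <- integer(0)
  for (o in max(1, theiler):(n - 1)) {
    run <- 0
    for (i in seq_len(n - o)) {
      if (R[i, i + o]) {
        run <- run + 1
      } else if (run > 0) {
        lens <- c(lens, run); run <- 0
      }
    }
    if (run > 0) lens <- c(lens, run)
  }
  if (length(lens) == 0) return(integer(0))
  tb <- table(lens)
  stats::setNames(as.integer(tb), names(tb))
}

brute_rqa_features <- function(P, lmin = 3) {
  if (length(P) == 0) return(list(det = NA, mdl = NA, ent = NA))
  l <- as.integer(names(P)); cnt <- as.numeric(P)
  det <- sum(l[l >= lmin] * cnt[l >= lmin]) / sum(l * cnt)
  if (any(l >= lmin)) {
    mdl <- sum(l[l >= lmin] * cnt[l >= lmin]) / sum(cnt[l >= lmin])
    p <- cnt[l >= lmin] / sum(cnt[l >= lmin])
    ent <- -sum(p * log(p))
  } else {
    mdl <- NA_real_; ent <- NA_real_
  }
  list(det = det, mdl = mdl, ent = ent)
}

# direct histogram AMI in nats (table-based, distinct code path)
brute_ami <- function(x, lag, bins = 16) {
  a <- x[seq_len(length(x) - lag)]
  b <- x[(1 + lag):length(x)]
  br <- seq(min(x), max(x), length.out = bins + 1)
  br[1] <- br[1] - 1e-9; br[bins + 1] <- br[bins + 1] + 1e-9
  J <- table(cut(a, br), cut(b, br)) / length(a)
  pa <- rowSums(J); pb <- colSums(J)
  s <- 0
  for (i in seq_len(bins)) {
    for (j in seq_len(bins)) {
      if (J[i, j] > 0) s <- s + J[i, j] * log(J[i, j] / (pa[i] * pb[j]))
    }
  }
  as.numeric(s)
}

# BH step-up by direct definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    v <- min(prev, m * p[o[k]] / k)
    adj[o[k]] <- v
    prev <- v
  }
  adj
}

# pairwise Mann-Whitney AUC by double loop
brute_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  s <- 0
  for (a in cs) for (b in ct) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cs) * length(ct))
}

make_sine <- function(n = 600, samples_per_period = 40.3, noise = 0,
                      seed = 1) {
  x <- sin(2 * pi * (0:(n - 1)) / samples_per_period)
  if (noise > 0) {
    set.seed(seed)
    x <- x + rnorm(n, 0, noise)
  }
  x
}

expect_series_equal <- function(a, b) {
  expect_identical(a$values, b$values)
  expect_identical(a$time, b$time)
}

class_labels_for_test <- function(tab) as.integer(tab$group == "case")
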