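#' @name rqa-module
#' @title Recurrence quantification analysis
#'
#' @description
#' Recurrence plots with an adaptive threshold epsilon chosen so that the
#' realized recurrence rate matches a fixed target (10% by default), and the
#' three diagonal-line features used downstream:
#'
#' * determinism: sum_(l >= lmin) l P(l) / sum_(l >= 1) l P(l), the fraction
#'   of recurrent points that lie on diagonal lines of length at least lmin;
#' * mean diagonal length: sum_(l >= lmin) l P(l) / sum_(l >= lmin) P(l);
#' * diagonal entropy: -sum_(l >= lmin) p(l) log p(l) in nats, with p the
#'   length distribution restricted to l >= lmin.
#'
#' P(l) is the histogram of maximal diagonal runs of recurrences. Pairs
#' closer to the main diagonal than the Theiler window are excluded; the
#' default window of 1 excludes only the line of identity.
NULL

#' RQA configuration
#'
#' @param target_recurrence_rate Target recurrence rate in (0, 1);
#'   default 0.10.
#' @param lmin Minimal diagonal length counted as cyclical (>= 2); default 3.
#' @param norm Distance norm, "euclidean" (default) or "maximum".
#' @param theiler_window Number of diagonals around (and including) the line
#'   of identity excluded from recurrences; 0 keeps everything, the default 1
#'   excludes only the identity.
#' @return An object of class `rqa_config`.
#' @export
rqa_config <- function(target_recurrence_rate = 0.10, lmin = 3,
                       norm = c("euclidean", "maximum"), theiler_window = 1) {
  norm <- match.arg(norm)
  stopifnot(target_recurrence_rate > 0, target_recurrence_rate <= 1,
            lmin >= 2, theiler_window >= 0)
  structure(list(target_recurrence_rate = target_recurrence_rate,
                 lmin = as.integer(lmin), norm = norm,
                 theiler_window = as.integer(theiler_window)),
            class = "rqa_config")
}

traj_dist <- function(trajectory, norm) {
  method <- if (norm == "maximum") "maximum" else "euclidean"
  as.matrix(stats::dist(trajectory$points, method = method))
}

# Off-Theiler pairwise distances (upper triangle; the identity pairs are
# appended when the Theiler window is 0 so they enter the rate denominator).
off_theiler_dists <- function(D, theiler_window) {
  n <- nrow(D)
  if (theiler_window <= 1L) {
    vals <- D[upper.tri(D)]
  } else {
    keep <- which(col(D) - row(D) >= theiler_window)
    vals <- D[keep]
  }
  if (theiler_window == 0L) vals <- c(vals, rep(0, n))
  vals
}

.adaptive_epsilon_D <- function(D, config) {
  dvals <- off_theiler_dists(D, config$theiler_window)
  if (length(dvals) == 0) stop("Theiler window leaves no pairs")
  if (diff(range(dvals)) == 0) {
    stop("degenerate geometry: all pairwise distances identical")
  }
  k <- max(1L, floor(config$target_recurrence_rate * length(dvals)))
  eps <- sort(dvals, partial = k)[k]
  structure(eps, realized_rate = mean(dvals <= eps))
}

.recurrence_from_D <- function(D, epsilon, config) {
  R <- D <= epsilon
  tw <- config$theiler_window
  if (tw == 1L) {
    diag(R) <- FALSE
  } else if (tw > 1L) {
    R[abs(row(R) - col(R)) < tw] <- FALSE
  }
  R
}

#' Adaptive recurrence threshold
#'
#' epsilon is the target-rate quantile of the off-Theiler pairwise distance
#' distribution: the k-th smallest distance with k = floor(target * N pairs)
#' (at least 1), so the realized rate equals the target up to the granularity
#' of the finite distance set.
#'
#' @param trajectory An [takens_embed()] result.
#' @param config An [rqa_config()].
#' @return epsilon, with attribute `realized_rate`.
#' @export
adaptive_epsilon <- function(trajectory, config = rqa_config()) {
  stopifnot(inherits(trajectory, "embedded_trajectory"))
  if (nrow(trajectory$points) < 2) stop("need at least 2 embedded points")
  .adaptive_epsilon_D(traj_dist(trajectory, config$norm), config)
}

#' Recurrence matrix at a given threshold
#'
#' Entry (i, j) is TRUE iff the embedded points i and j are within `epsilon`
#' of each other and |i - j| is not inside the Theiler window.
#'
#' @inheritParams adaptive_epsilon
#' @param epsilon Distance threshold.
#' @return An object of class `recurrence_result` with fields `matrix`
#'   (logical, symmetric), `epsilon`, `recurrence_rate` (over off-Theiler
#'   pairs), `theiler_window`.
#' @export
recurrence_matrix <- function(trajectory, epsilon, config = rqa_config()) {
  stopifnot(inherits(trajectory, "embedded_trajectory"))
  D <- traj_dist(trajectory, config$norm)
  R <- .recurrence_from_D(D, epsilon, config)
  dvals <- off_theiler_dists(D, config$theiler_window)
  rate <- if (length(dvals) > 0) mean(dvals <= epsilon) else NA_real_
  structure(list(matrix = R, epsilon = as.numeric(epsilon),
                 recurrence_rate = rate,
                 theiler_window = config$theiler_window),
            class = "recurrence_result")
}

#' Histogram of diagonal line lengths
#'
#' Counts maximal runs of recurrences along each superdiagonal of the matrix
#' (the upper triangle only; symmetry makes the lower triangle redundant).
#' The line of identity is never counted. Runs truncated by the matrix border
#' count at their observed length.
#'
#' @param mat Logical (or 0/1) recurrence matrix, or a `recurrence_result`.
#' @param theiler_window Diagonals |i - j| < theiler_window are skipped.
#' @return Named integer vector mapping line length l to its count P(l)
#'   (lengths with zero count omitted; empty vector if there are no lines).
#' @export
diagonal_histogram <- function(mat, theiler_window = 1) {
  if (inherits(mat, "recurrence_result")) {
    theiler_window <- mat$theiler_window
    mat <- mat$matrix
  }
  mat <- mat != 0
  n <- nrow(mat)
  o0 <- max(1L, theiler_window)
  if (o0 > n - 1) return(stats::setNames(integer(0), character(0)))
  os <- o0:(n - 1L)
  dlens <- n - os
  # linear indices of every superdiagonal, FALSE separators between them,
  # one run-length pass over the lot
  starts <- (n + 1) + (os - 1) * n
  lin <- sequence(dlens, from = starts, by = n + 1L)
  total <- sum(dlens) + length(dlens)
  v <- logical(total)
  keep_pos <- seq_len(total)[-cumsum(dlens + 1L)]
  v[keep_pos] <- mat[lin]
  r <- rle(v)
  lens <- r$lengths[r$values]
  if (length(lens) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- tabulate(lens)
  nzl <- which(tab > 0)
  stats::setNames(tab[nzl], nzl)
}

hist_lengths <- function(P) as.integer(names(P))

#' Determinism
#'
#' Fraction of recurrent points on diagonal lines of length >= lmin:
#' sum_(l >= lmin) l P(l) / sum_(l >= 1) l P(l).
#'
#' @param P Diagonal-line histogram from [diagonal_histogram()].
#' @param lmin Minimal qualifying length (default 3).
#' @return Value in \[0, 1\], or `NA` if the histogram is empty.
#' @export
determinism <- function(P, lmin = 3) {
  if (length(P) == 0) return(NA_real_)
  l <- hist_lengths(P)
  tot <- sum(l * P)
  if (tot == 0) return(NA_real_)
  sum((l * P)[l >= lmin]) / tot
}

#' Mean diagonal length
#'
#' sum_(l >= lmin) l P(l) / sum_(l >= lmin) P(l); `NA` when no line reaches
#' lmin.
#'
#' @inheritParams determinism
#' @export
mean_diagonal_length <- function(P, lmin = 3) {
  if (length(P) == 0) return(NA_real_)
  l <- hist_lengths(P)
  keep <- l >= lmin
  if (!any(keep) || sum(P[keep]) == 0) return(NA_real_)
  sum((l * P)[keep]) / sum(P[keep])
}

#' Diagonal-line entropy
#'
#' Shannon entropy (nats) of the diagonal length distribution restricted to
#' l >= lmin: -sum p(l) log p(l). Zero iff a single length class is present;
#' `NA` when no line reaches lmin.
#'
#' @inheritParams determinism
#' @export
diagonal_entropy <- function(P, lmin = 3) {
  if (length(P) == 0) return(NA_real_)
  l <- hist_lengths(P)
  keep <- l >= lmin & P > 0
  if (!any(keep)) return(NA_real_)
  p <- P[keep] / sum(P[keep])
  -sum(p * log(p))
}

#' Recurrence quantification analysis of a series
#'
#' End-to-end pipeline: estimate the delay (AMI first local minimum) and
#' dimension (FNN) unless given, build the Takens embedding, choose the
#' adaptive threshold at the target recurrence rate, and compute the
#' recurrence matrix, diagonal histogram, and the three features.
#'
#' @param series A [biomarker_series()] or numeric vector.
#' @param delay,dimension Embedding parameters; estimated when `NULL`.
#' @param config An [rqa_config()].
#' @param max_lag,bins Passed to [estimate_delay()].
#' @param max_dim Passed to [estimate_dimension()].
#' @param keep_matrix Keep the recurrence matrix in the result (default TRUE;
#'   set FALSE to save memory in cohort runs).
#' @return An object of class `rqa`: list with `delay`, `dimension`,
#'   `epsilon`, `recurrence_rate`, `diag_histogram`, `determinism`,
#'   `mean_diagonal_length`, `entropy`, `config`, `n_points`, and (optionally)
#'   `matrix`.
#' @examples
#' t <- seq(0, 10, by = 1 / 48)
#' r <- rqa(biomarker_series(t, sin(2 * pi * 1.2 * t)))
#' summary(r)
#' @export
rqa <- function(series, delay = NULL, dimension = NULL, config = rqa_config(),
                max_lag = 25, bins = 16, max_dim = 6, keep_matrix = TRUE) {
  x <- series_values(series)
  if (is.null(delay)) delay <- as.integer(estimate_delay(x, max_lag, bins))
  if (is.null(dimension)) {
    dimension <- as.integer(estimate_dimension(x, delay, max_dim))
  }
  traj <- takens_embed(x, delay, dimension)
  D <- traj_dist(traj, config$norm)
  eps <- .adaptive_epsilon_D(D, config)
  R <- .recurrence_from_D(D, as.numeric(eps), config)
  P <- diagonal_histogram(R, config$theiler_window)
  out <- list(delay = delay, dimension = dimension,
              epsilon = as.numeric(eps),
              target_recurrence_rate = config$target_recurrence_rate,
              recurrence_rate = attr(eps, "realized_rate"),
              diag_histogram = P,
              determinism = determinism(P, config$lmin),
              mean_diagonal_length = mean_diagonal_length(P, config$lmin),
              entropy = diagonal_entropy(P, config$lmin),
              config = config, n_points = nrow(traj$points))
  if (keep_matrix) out$matrix <- R
  structure(out, class = "rqa")
}

#' @export
print.rqa <- function(x, ...) {
  cat(sprintf(
    "<rqa> m = %d, tau = %d, eps = %.4g (rate %.3f, target %.2f)\n",
    x$dimension, x$delay, x$epsilon, x$recurrence_rate,
    x$target_recurrence_rate))
  cat(sprintf("  DET = %.3f  MDL = %.3f  ENT = %.3f (lmin = %d)\n",
              x$determinism, x$mean_diagonal_length, x$entropy,
              x$config$lmin))
  invisible(x)
}

#' @export
summary.rqa <- function(object, ...) {
  print(object)
  P <- object$diag_histogram
  if (length(P)) {
    cat(sprintf("  diagonal lines: %d, lengths %s-%s\n", sum(P),
                names(P)[1], names(P)[length(P)]))
  }
  invisible(object)
}

#' @export
plot.rqa <- function(x, ...) {
  if (is.null(x$matrix)) stop("recurrence matrix not kept; rerun with keep_matrix = TRUE")
  n <- nrow(x$matrix)
  graphics::image(1:n, 1:n, t(x$matrix[n:1, ]), col = c("white", "black"),
                  xlab = "index", ylab = "index", main = "recurrence plot",
                  useRaster = TRUE, ...)
  invisible(x)
}
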