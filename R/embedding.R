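#' @name embedding
#' @title Delay embedding and parameter selection
#'
#' @description
#' Phase-space reconstruction of a univariate series by Takens delay
#' embedding. The delay tau is chosen as the first local minimum of the
#' average mutual information (AMI) between the series and its lagged copy;
#' the dimension m as the smallest dimension at which the fraction of false
#' nearest neighbours (Kennel criteria) drops below a threshold.
NULL

#' Average mutual information between a series and its lagged copy
#'
#' AMI (in nats) between z_t and z_(t+lag) estimated from a joint histogram.
#' With equal-width binning (the default) AMI depends on the value scale only
#' through the bin edges; with `binning = "quantile"` it is invariant under
#' strictly monotone rescaling of the values.
#'
#' @param series A [biomarker_series()] or numeric vector.
#' @param lag Integer lag, 0 <= |lag| < n; the sign is irrelevant.
#' @param bins Number of marginal histogram bins (>= 2).
#' @param binning "width" (equal-width, default) or "quantile".
#' @return AMI in nats (>= 0). A constant series yields 0 with a warning.
#' @export
average_mutual_information <- function(series, lag, bins = 16,
                                       binning = c("width", "quantile")) {
  x <- series_values(series)
  binning <- match.arg(binning)
  lag <- abs(as.integer(lag))
  n <- length(x)
  if (lag >= n) stop("`lag` must be < length of series")
  if (bins < 2) stop("`bins` must be >= 2")
  if (diff(range(x)) == 0) {
    warning("constant series: AMI defined as 0 (degenerate histogram)")
    return(0)
  }
  edges <- if (binning == "width") {
    seq(min(x), max(x), length.out = bins + 1)
  } else {
    unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                           names = FALSE, type = 1))
  }
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- max(b)
  a <- b[seq_len(n - lag)]
  c <- b[(1 + lag):n]
  joint <- tabulate(a + nb * (c - 1L), nbins = nb * nb)
  joint <- joint / sum(joint)
  px <- tabulate(a, nbins = nb) / length(a)
  py <- tabulate(c, nbins = nb) / length(c)
  pxy_ind <- as.vector(outer(px, py))
  pos <- joint > 0
  max(0, sum(joint[pos] * log(joint[pos] / pxy_ind[pos])))
}

#' Estimate the embedding delay from the AMI curve
#'
#' Returns the smallest lag in `[1, max_lag]` that is a strict local minimum
#' of the AMI curve (plateaus take their left edge). If the curve has no
#' interior local minimum, the global minimizer is returned with a warning
#' and the attribute `no_local_minimum = TRUE`.
#'
#' @inheritParams average_mutual_information
#' @param max_lag Largest lag examined (>= 2).
#' @return Integer delay, with attributes `ami` (the curve for lags
#'   0..max_lag) and `no_local_minimum`.
#' @export
estimate_delay <- function(series, max_lag = 25, bins = 16,
                           binning = c("width", "quantile")) {
  x <- series_values(series)
  binning <- match.arg(binning)
  if (max_lag < 2) stop("`max_lag` must be >= 2")
  if (length(x) < max_lag + 2) {
    stop("series too short (", length(x), ") for max_lag = ", max_lag)
  }
  ami <- vapply(0:max_lag, function(l) {
    suppressWarnings(average_mutual_information(x, l, bins, binning))
  }, numeric(1))
  # first strict local minimum; plateaus collapse to the left edge
  found <- NA_integer_
  for (l in 1:(max_lag - 1)) {
    if (ami[l + 1] < ami[l]) {       # ami[l+1] is the value at lag l
      j <- l + 1
      while (j < max_lag + 1 && ami[j + 1] == ami[l + 1]) j <- j + 1
      if (j <= max_lag && ami[j + 1] > ami[l + 1]) { found <- l; break }
    }
  }
  flag <- is.na(found)
  if (flag) {
    found <- which.min(ami[-1])
    warning("AMI curve has no interior local minimum up to max_lag = ",
            max_lag, "; returning the global minimizer")
  }
  structure(as.integer(found), ami = ami, no_local_minimum = flag)
}

#' Fraction of false nearest neighbours at a given dimension
#'
#' For each point of the `dim`-dimensional embedding whose lift to
#' `dim + 1` is defined, the nearest neighbour is found and flagged false by
#' the Kennel criteria: the extra-coordinate separation exceeds `rtol` times
#' the neighbour distance, or the lifted distance exceeds `atol` times the
#' attractor size (the standard deviation of the series).
#'
#' @inheritParams average_mutual_information
#' @param delay Embedding delay (samples).
#' @param dim Embedding dimension tested.
#' @param rtol Ratio threshold (Kennel criterion 1), default 10.
#' @param atol Attractor-size threshold (Kennel criterion 2), default 2.
#' @return Fraction in \[0, 1\]. A series of identical values returns 0 with
#'   a warning.
#' @export
fnn_fraction <- function(series, delay, dim, rtol = 10, atol = 2) {
  x <- series_values(series)
  n <- length(x)
  npts <- n - dim * delay               # points whose lift exists
  if (npts < 10) {
    stop("fewer than 10 embedded points at dim + 1 = ", dim + 1,
         " (n = ", n, ", delay = ", delay, ")")
  }
  if (diff(range(x)) == 0) {
    warning("all values identical: FNN fraction defined as 0")
    return(0)
  }
  # nearest-neighbour scan in compiled code; neighbours coincident up to
  # roundoff (below 1e-8 * attractor size) stay true neighbours, otherwise
  # exactly periodic signals produce ratios of machine-epsilon quantities
  .Call(C_fnn_fraction, as.double(x), as.integer(npts), as.integer(delay),
        as.integer(dim), as.double(rtol), as.double(atol),
        as.double(stats::sd(x)))
}

#' Estimate the embedding dimension by false nearest neighbours
#'
#' The smallest m <= max_dim with FNN fraction below `threshold`; if none,
#' `max_dim` is returned with a warning and attribute
#' `no_dimension_found = TRUE`.
#'
#' @inheritParams fnn_fraction
#' @param max_dim Largest dimension examined.
#' @param threshold False-neighbour fraction considered negligible
#'   (default 1%).
#' @return Integer dimension with attributes `fnn` (fractions for
#'   1..returned dim) and `no_dimension_found`.
#' @export
estimate_dimension <- function(series, delay, max_dim = 6, rtol = 10,
                               atol = 2, threshold = 0.01) {
  x <- series_values(series)
  if (diff(range(x)) == 0) {
    return(structure(1L, fnn = 0, no_dimension_found = FALSE))
  }
  fr <- numeric(0)
  for (m in seq_len(max_dim)) {
    f <- suppressWarnings(fnn_fraction(x, delay, m, rtol, atol))
    fr <- c(fr, f)
    if (f < threshold) {
      return(structure(as.integer(m), fnn = fr, no_dimension_found = FALSE))
    }
  }
  warning("FNN fraction stayed >= ", threshold, " up to max_dim = ", max_dim)
  structure(as.integer(max_dim), fnn = fr, no_dimension_found = TRUE)
}

#' Takens delay embedding
#'
#' Builds the lag matrix whose row i is
#' (z_i, z_(i+tau), ..., z_(i+(m-1)tau)).
#'
#' @inheritParams fnn_fraction
#' @param dim Embedding dimension m (>= 1).
#' @return An object of class `embedded_trajectory`: list with `points`
#'   (an (n - (m-1) tau) x m matrix), `delay`, `dim`.
#' @examples
#' takens_embed(1:5, delay = 1, dim = 2)$points
#' @export
takens_embed <- function(series, delay, dim) {
  x <- series_values(series)
  n <- length(x)
  delay <- as.integer(delay); dim <- as.integer(dim)
  if (delay < 1 || dim < 1) stop("`delay` and `dim` must be >= 1")
  nrow <- n - (dim - 1) * delay
  if (nrow < 1) {
    stop(sprintf("embedding infeasible: n = %d, m = %d, tau = %d", n, dim,
                 delay))
  }
  pts <- matrix(0, nrow, dim)
  for (k in seq_len(dim)) {
    pts[, k] <- x[(1 + (k - 1) * delay):(nrow + (k - 1) * delay)]
  }
  structure(list(points = pts, delay = delay, dim = dim),
            class = "embedded_trajectory")
}

#' @export
print.embedded_trajectory <- function(x, ...) {
  cat(sprintf("<embedded_trajectory> %d points, m = %d, tau = %d\n",
              nrow(x$points), x$dim, x$delay))
  invisible(x)
}

#' Median embedding parameters across a cohort
#'
#' Per-element medians of the per-subject delay and dimension estimates;
#' subjects are still embedded with their own estimates, the medians are
#' reported for cohort summaries.
#'
#' @param params Data frame with columns `element`, `tau`, `m` (as produced
#'   by [extract_features()] in its `params` attribute).
#' @return Data frame with per-element median tau and m.
#' @export
median_embedding_params <- function(params) {
  stopifnot(all(c("element", "tau", "m") %in% names(params)))
  out <- do.call(rbind, lapply(split(params, params$element), function(d) {
    data.frame(element = d$element[1],
               median_tau = stats::median(d$tau, na.rm = TRUE),
               median_m = stats::median(d$m, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
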