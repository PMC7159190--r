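#' @name potential-module
#' @title Potential energy landscapes and quasi-stable state counting
#'
#' @description
#' Treats a standardized concentration series as the output of a stochastic
#' gradient system whose stationary density Pd determines, via the
#' steady-state Fokker-Planck relation, a potential U = -(sigma^2 / 2) log Pd.
#' Potentials are reported on the noise-scaled axis U / sigma^2, so with the
#' series standardized to unit variance the working formula is
#' U = -log(Pd) / 2. Local minima of U are quasi-stable attractor states;
#' the local maximum between two adjacent states is the tipping point
#' separating their basins.
NULL

#' Standardize a series to unit standard deviation
#'
#' Mean-centers and scales to sample SD 1. The landscape is invariant to
#' translation, so centering is cosmetic; scaling fixes the noise level to 1.
#' Original location/scale are retained as attributes `center` and `scale`.
#'
#' @param series A [biomarker_series()] or numeric vector.
#' @return Same type as the input, standardized; errors on a constant series.
#' @export
standardize <- function(series) {
  x <- series_values(series)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("constant series: zero variance")
  m <- mean(x)
  z <- (x - m) / s
  if (inherits(series, "biomarker_series")) {
    out <- series
    out$values <- z
  } else {
    out <- z
  }
  attr(out, "center") <- m
  attr(out, "scale") <- s
  out
}

#' Gaussian kernel density with Scott bandwidth
#'
#' Kernel density estimate with bandwidth sd(x) * n^(-1/5) (Scott's rule),
#' evaluated on a regular grid spanning the data range padded by three
#' bandwidths on both sides.
#'
#' @param values Numeric sample (>= 10 observations, >= 2 distinct values).
#' @param grid_size Number of grid points (default 500).
#' @param bw Bandwidth override; default Scott's rule.
#' @return List with `grid`, `density`, `bw`.
#' @export
estimate_density <- function(values, grid_size = 500, bw = NULL) {
  x <- as.numeric(values)
  if (length(x) < 10) stop("need at least 10 observations for the KDE")
  if (length(unique(x)) < 2) stop("need at least 2 distinct values")
  if (is.null(bw)) bw <- stats::sd(x) * length(x)^(-1 / 5)
  d <- stats::density(x, bw = bw, kernel = "gaussian",
                      from = min(x) - 3 * bw, to = max(x) + 3 * bw,
                      n = grid_size)
  list(grid = d$x, density = d$y, bw = bw)
}

#' Potential from a probability density
#'
#' U = -(sigma^2 / 2) log Pd, then scaled by the noise level to U / sigma^2,
#' which removes sigma altogether: the returned potential is -log(Pd) / 2.
#' A tiny numerical floor is applied before the logarithm so empty grid
#' cells give large finite potentials rather than infinities; state finding
#' applies its own, much higher, density floor.
#'
#' @param density Density values on a grid (>= 0).
#' @param sigma Noise level (retained for the unscaled variant).
#' @param scaled Return U / sigma^2 (default) or U itself.
#' @return Numeric potential on the same grid.
#' @export
potential_from_density <- function(density, sigma = 1, scaled = TRUE) {
  if (any(density < 0)) stop("`density` must be non-negative")
  u <- -(sigma^2 / 2) * log(pmax(density, 1e-300))
  if (scaled) u / sigma^2 else u
}

# Strict sign-change extrema of u with plateaus collapsed to their leftmost
# point. Returns interior indices of minima and maxima.
sign_change_extrema <- function(u) {
  du <- diff(u)
  nz <- which(du != 0)
  mins <- integer(0); maxs <- integer(0)
  if (length(nz) >= 2) {
    s <- sign(du[nz])
    for (k in seq_len(length(nz) - 1)) {
      if (s[k] < 0 && s[k + 1] > 0) mins <- c(mins, nz[k] + 1L)
      if (s[k] > 0 && s[k + 1] < 0) maxs <- c(maxs, nz[k] + 1L)
    }
  }
  list(minima = mins, maxima = maxs)
}

#' Locate quasi-stable states and tipping points
#'
#' Finds interior sign-change minima of the potential, keeping only minima
#' whose density is at least `floor_fraction` of the maximal density (minima
#' supported by negligible probability mass are KDE tail artifacts, since
#' -log Pd diverges in empty tails). Each tipping point is the maximum of
#' the potential between two consecutive retained minima, so minima and
#' maxima strictly alternate. A landscape with no admissible interior
#' minimum reports the global admissible minimum as its single state.
#'
#' @param landscape A list with `grid`, `density`, `potential` (e.g. a
#'   [potential_landscape()]), or passed individually.
#' @param floor_fraction Density floor relative to the density maximum
#'   (default 0.05).
#' @return List with `minima`, `maxima` (grid locations), `minima_idx`,
#'   `maxima_idx`, `n_states`.
#' @export
find_states <- function(landscape, floor_fraction = 0.05) {
  grid <- landscape$grid; dens <- landscape$density
  u <- landscape$potential
  if (length(grid) < 10) stop("potential must be defined on >= 10 grid points")
  admissible <- dens >= floor_fraction * max(dens)
  ex <- sign_change_extrema(u)
  mins <- ex$minima[admissible[ex$minima]]
  if (length(mins) == 0) {
    idx_adm <- which(admissible)
    mins <- idx_adm[which.min(u[idx_adm])]
  }
  maxs <- integer(0)
  if (length(mins) > 1) {
    for (k in seq_len(length(mins) - 1)) {
      seg <- (mins[k] + 1L):(mins[k + 1] - 1L)
      maxs <- c(maxs, seg[which.max(u[seg])])
    }
  }
  list(minima = grid[mins], maxima = grid[maxs],
       minima_idx = mins, maxima_idx = maxs,
       n_states = length(mins))
}

#' Potential energy landscape of a series
#'
#' Orchestrates standardize -> Gaussian KDE (Scott bandwidth) -> potential
#' -> state finding on the full series.
#'
#' @param series A [biomarker_series()] or numeric vector.
#' @param grid_size Density grid size (default 500).
#' @param floor_fraction Density floor for state finding (default 0.05).
#' @param standardize Standardize to unit SD first (default TRUE).
#' @return An object of class `potential_landscape`: `grid`, `density`,
#'   `potential`, `bw`, `minima`, `maxima`, `n_states`, `center`, `scale`.
#' @examples
#' set.seed(1)
#' pl <- potential_landscape(c(rnorm(200, -1.5, 0.3), rnorm(200, 1.5, 0.3)))
#' pl$n_states
#' @export
potential_landscape <- function(series, grid_size = 500,
                                floor_fraction = 0.05, standardize = TRUE) {
  x <- series_values(series)
  center <- 0; scale <- 1
  if (standardize) {
    z <- standardize(x)
    center <- attr(z, "center"); scale <- attr(z, "scale")
    x <- as.numeric(z)
  }
  kde <- estimate_density(x, grid_size)
  u <- potential_from_density(kde$density)
  st <- find_states(list(grid = kde$grid, density = kde$density,
                         potential = u), floor_fraction)
  structure(list(grid = kde$grid, density = kde$density, potential = u,
                 bw = kde$bw, minima = st$minima, maxima = st$maxima,
                 minima_idx = st$minima_idx, maxima_idx = st$maxima_idx,
                 n_states = st$n_states, center = center, scale = scale,
                 floor_fraction = floor_fraction),
            class = "potential_landscape")
}

#' @export
print.potential_landscape <- function(x, ...) {
  cat(sprintf("<potential_landscape> %d quasi-stable state(s) at %s",
              x$n_states, paste(sprintf("%.2f", x$minima), collapse = ", ")))
  if (length(x$maxima)) {
    cat(sprintf("; tipping point(s) at %s",
                paste(sprintf("%.2f", x$maxima), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
plot.potential_landscape <- function(x, ...) {
  keep <- x$density >= x$floor_fraction * max(x$density)
  graphics::plot(x$grid[keep], x$potential[keep], type = "l",
                 xlab = "standardized concentration",
                 ylab = expression(U / sigma^2), ...)
  graphics::points(x$minima, x$potential[x$minima_idx], col = "red", pch = 19)
  if (length(x$maxima)) {
    graphics::points(x$maxima, x$potential[x$maxima_idx], col = "blue",
                     pch = 17)
  }
  invisible(x)
}

#' Count quasi-stable states of a series
#'
#' @inheritParams potential_landscape
#' @return Integer number of local potential minima (>= 1).
#' @export
count_states <- function(series, grid_size = 500, floor_fraction = 0.05) {
  potential_landscape(series, grid_size, floor_fraction)$n_states
}

#' Rolling-window potential landscapes
#'
#' The series is standardized once; each window of `window_length`
#' consecutive samples then gets its own KDE (Scott bandwidth within the
#' window) and potential, all evaluated on one common grid spanning the full
#' standardized range, so windows are directly comparable and the result can
#' be rendered as a time-by-concentration surface.
#'
#' @param series A [biomarker_series()] or numeric vector.
#' @param window_length Samples per window (default 50).
#' @param step Window stride in samples (default 1, fully rolling).
#' @param grid_size Common grid size (default 200).
#' @param floor_fraction Density floor for per-window state counts.
#' @return An object of class `rolling_landscape`: `grid`, `potential`
#'   (windows x grid matrix), `density` (same shape), `window_centers`
#'   (times), `n_states` (per window), `window_length`, `step`.
#' @export
rolling_landscape <- function(series, window_length = 50, step = 1,
                              grid_size = 200, floor_fraction = 0.05) {
  x <- series_values(series)
  tm <- series_time(series, length(x))
  n <- length(x)
  if (window_length > n) {
    stop("`window_length` (", window_length, ") exceeds series length (", n,
         ")")
  }
  z <- as.numeric(standardize(x))
  bw_ref <- stats::sd(z) * window_length^(-1 / 5)
  grid <- seq(min(z) - 3 * bw_ref, max(z) + 3 * bw_ref,
              length.out = grid_size)
  starts <- seq(1, n - window_length + 1, by = step)
  pot <- matrix(NA_real_, length(starts), grid_size)
  den <- matrix(NA_real_, length(starts), grid_size)
  ns <- integer(length(starts))
  for (k in seq_along(starts)) {
    w <- z[starts[k]:(starts[k] + window_length - 1)]
    if (stats::sd(w) == 0) { ns[k] <- 1L; next }
    bw <- stats::sd(w) * window_length^(-1 / 5)
    d <- stats::density(w, bw = bw, from = grid[1], to = grid[grid_size],
                        n = grid_size)
    den[k, ] <- d$y
    pot[k, ] <- potential_from_density(d$y)
    ns[k] <- find_states(list(grid = grid, density = d$y,
                              potential = pot[k, ]),
                         floor_fraction)$n_states
  }
  centers <- tm[starts + floor(window_length / 2)]
  structure(list(grid = grid, potential = pot, density = den,
                 window_centers = centers, n_states = ns,
                 window_length = as.integer(window_length),
                 step = as.integer(step)),
            class = "rolling_landscape")
}

#' @export
print.rolling_landscape <- function(x, ...) {
  cat(sprintf("<rolling_landscape> %d windows of %d samples, grid %d\n",
              nrow(x$potential), x$window_length, length(x$grid)))
  invisible(x)
}

#' @export
plot.rolling_landscape <- function(x, cap = NULL, ...) {
  u <- x$potential
  if (is.null(cap)) cap <- stats::quantile(u[is.finite(u)], 0.98)
  u[u > cap] <- cap
  graphics::filled.contour(
    x$window_centers, x$grid, u,
    xlab = "time since birth (years)", ylab = "standardized concentration",
    main = expression("rolling potential " * U / sigma^2), ...)
  invisible(x)
}
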