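test_that("standardize fixes the SD at one and errors on constants", {
  z <- standardize(c(0, 2))
  expect_equal(sd(z), 1)
  expect_equal(attr(z, "scale"), sd(c(0, 2)))
  set.seed(1)
  x <- rnorm(50)
  x <- (x - mean(x)) / sd(x)
  expect_equal(as.numeric(standardize(x)), x, tolerance = 1e-12)
  expect_error(standardize(rep(4, 20)), "zero variance")
  s <- biomarker_series(1:20, rnorm(20))
  expect_equal(sd(standardize(s)$values), 1)
})

test_that("KDE uses Scott bandwidth, integrates to one, recovers the mode", {
  set.seed(2)
  x <- rnorm(5e4)
  kde <- estimate_density(x)
  expect_equal(kde$bw, sd(x) * length(x)^(-1 / 5))
  expect_equal(sum(diff(kde$grid) *
                     (head(kde$density, -1) + tail(kde$density, -1)) / 2),
               1, tolerance = 0.01)
  # smoothing bias at the mode is ~ bw^2 |f''(0)| / 2 ~ 0.003 at this n;
  # allow it plus sampling noise
  expect_equal(kde$density[which.min(abs(kde$grid))], dnorm(0),
               tolerance = 0.02)
  expect_error(estimate_density(rnorm(5)), "at least 10")
  expect_error(estimate_density(rep(1, 20)), "distinct")
  # two-point sample: mixture of two kernel bumps
  kde2 <- estimate_density(rep(c(-2, 2), 10))
  st <- find_states(list(grid = kde2$grid, density = kde2$density,
                         potential = potential_from_density(kde2$density)))
  expect_equal(st$n_states, 2)
})

test_that("potential of an exact normal density is quadratic z^2/4", {
  zg <- seq(-3, 3, length.out = 500)
  u <- potential_from_density(dnorm(zg))
  fit <- lm(u ~ poly(zg, 2, raw = TRUE))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)
  expect_equal(unname(coef(fit)[3]), 0.25, tolerance = 1e-6)
  # uniform density: flat potential
  expect_equal(diff(range(potential_from_density(rep(0.2, 100)))), 0)
  expect_error(potential_from_density(c(0.1, -0.2)), "non-negative")
})

test_that("closed-form bimodal mixture yields two states and one tipping point", {
  zg <- seq(-3, 3, length.out = 500)
  dens <- 0.5 * dnorm(zg, -1.5, 0.3) + 0.5 * dnorm(zg, 1.5, 0.3)
  u <- potential_from_density(dens)
  st <- find_states(list(grid = zg, density = dens, potential = u),
                    floor_fraction = 0.05)
  step <- diff(zg)[1]
  expect_equal(st$n_states, 2)
  expect_lt(abs(st$minima[1] + 1.5), step + 1e-9)
  expect_lt(abs(st$minima[2] - 1.5), step + 1e-9)
  expect_length(st$maxima, 1)
  expect_lt(abs(st$maxima[1]), step + 1e-9)
})

test_that("unimodal landscapes report one state and no tipping points", {
  zg <- seq(-4, 4, length.out = 300)
  dens <- dnorm(zg)
  st <- find_states(list(grid = zg, density = dens,
                         potential = potential_from_density(dens)))
  expect_equal(st$n_states, 1)
  expect_length(st$maxima, 0)
  expect_error(find_states(list(grid = 1:5, density = rep(1, 5),
                                potential = rep(1, 5))), ">= 10")
})

test_that("landscape minimum coincides with the density mode", {
  set.seed(3)
  for (k in 1:5) {
    x <- rnorm(300, sample(-2:2, 1), runif(1, 0.5, 2))
    pl <- potential_landscape(x)
    expect_equal(which.min(replace(pl$potential,
                                   pl$density < 0.05 * max(pl$density), Inf)),
                 which.max(pl$density))
  }
})

test_that("state counts are invariant to affine transformations", {
  dw <- double_well_spec()
  x <- simulate_langevin(dw, 400, 1 / 48, seed = 5, substeps = 8,
                         burn_in = 100)$values
  n0 <- count_states(x)
  expect_equal(count_states(x + 100), n0)
  expect_equal(count_states(x * 7), n0)
  expect_equal(count_states(x * 0.01 - 3), n0)
})

test_that("minima and maxima strictly alternate on random landscapes", {
  set.seed(6)
  for (k in 1:10) {
    x <- c(rnorm(150, -2), rnorm(sample(c(50, 150), 1), 2),
           rnorm(sample(c(0, 100), 1), 5))
    pl <- potential_landscape(x)
    expect_equal(length(pl$maxima), pl$n_states - 1)
    if (pl$n_states > 1) {
      pos <- sort(c(pl$minima_idx, pl$maxima_idx))
      types <- ifelse(pos %in% pl$minima_idx, "min", "max")
      expect_true(all(types[seq(1, length(types), 2)] == "min"))
      expect_true(all(types[seq(2, length(types), 2)] == "max"))
    }
  }
})

test_that("mono-, bi-, and tri-stable draws are counted correctly", {
  # OU: single attractor
  ou <- simulate_langevin(ou_spec(), 400, 1 / 48, seed = 7, substeps = 8,
                          burn_in = 100)
  expect_equal(count_states(ou), 1)
  # double well: two attractors
  dw <- simulate_langevin(double_well_spec(), 450, 1 / 48, seed = 7,
                          substeps = 8, burn_in = 100)
  expect_equal(count_states(dw), 2)
  # trimodal mixture draw: three
  set.seed(8)
  tri <- c(rnorm(200, -4, 0.5), rnorm(200, 0, 0.5), rnorm(200, 4, 0.5))
  expect_equal(count_states(tri), 3)
})

test_that("state detection rises with barrier height", {
  # detection curve over barrier heights; at very low barriers the density
  # top is nearly flat and detection is noisy, so monotonicity is asserted
  # up to one seed's worth of simulation slack
  seeds <- 1:16
  frac2 <- vapply(c(0.5, 2, 6), function(b) {
    mean(vapply(seeds, function(s) {
      x <- simulate_langevin(double_well_spec(barrier = b), 400, 1 / 48,
                             seed = s, substeps = 8, burn_in = 100)
      count_states(x) >= 2
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(frac2) >= -1 / length(seeds)))
  expect_gt(frac2[3], 0.9)
  expect_gt(frac2[3], frac2[1])
})

test_that("rolling landscapes track regime shifts", {
  # stationary OU: every window mono-stable
  ou <- simulate_langevin(ou_spec(), 220, 1 / 48, seed = 9, substeps = 8,
                          burn_in = 100)
  rl <- rolling_landscape(ou, window_length = 50, step = 10)
  expect_true(mean(rl$n_states == 1) >= 0.9)
  expect_equal(ncol(rl$potential), length(rl$grid))
  # mean shift > 3 SD at mid-series: straddling windows see two states
  set.seed(10)
  x <- c(rnorm(150, 0, 0.5), rnorm(150, 4, 0.5))
  rs <- rolling_landscape(x, window_length = 50, step = 5)
  mid <- which(abs(seq_along(rs$n_states) -
                     which.min(abs(rs$window_centers - 150))) <= 2)
  expect_true(any(rs$n_states[mid] >= 2))
  expect_error(rolling_landscape(rnorm(30), window_length = 50), "exceeds")
})
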