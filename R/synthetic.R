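#' @name synthetic
#' @title Synthetic biomarker series and cohorts
#'
#' @description
#' Generators that emulate the statistical structure of dentine elemental
#' profiles: long (300-600 sample) series on a uniform, roughly weekly time
#' grid spanning early development, either switching stochastically between
#' quasi-stable states (overdamped Langevin motion in a confining polynomial
#' well) or alternating between deterministic oscillatory regimes (piecewise
#' sinusoids with observation noise). Cohort-level generators plant
#' case/control differences in state count and periodicity.
NULL

## ---- seed hygiene -----------------------------------------------------------

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## ---- polynomial helpers -----------------------------------------------------

# ascending coefficients c0 + c1 z + c2 z^2 + ...
polyval <- function(coef, z) {
  out <- rep(coef[length(coef)], length(z))
  for (k in rev(seq_len(length(coef) - 1))) out <- out * z + coef[k]
  out
}

polyderiv <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}

## ---- specs ------------------------------------------------------------------

#' Specify a confining polynomial potential well
#'
#' Defines the overdamped Langevin system dz = -V'(z) dt + sigma dW, where V
#' is a polynomial in `coefficients` (ascending order). V must be confining:
#' even degree >= 2 with a positive leading coefficient, so trajectories
#' cannot escape to infinity.
#'
#' @param coefficients Numeric vector of polynomial coefficients of V(z),
#'   ascending (constant term first).
#' @param sigma Diffusion amplitude (> 0).
#' @param z0 Initial state.
#' @return An object of class `well_spec`.
#' @seealso [double_well_spec()], [ou_spec()], [simulate_langevin()]
#' @export
well_spec <- function(coefficients, sigma, z0 = 0) {
  coefficients <- as.numeric(coefficients)
  nz <- which(coefficients != 0)
  if (length(nz) == 0) stop("potential polynomial is identically zero")
  degree <- max(nz) - 1L
  if (degree < 2 || degree %% 2 != 0 || coefficients[max(nz)] <= 0) {
    stop("non-confining potential: polynomial degree must be even, >= 2, ",
         "with positive leading coefficient")
  }
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a positive scalar")
  }
  structure(list(coefficients = coefficients, sigma = sigma, z0 = z0,
                 degree = degree),
            class = "well_spec")
}

#' Symmetric double-well specification
#'
#' V(z) = barrier * (z^2 - 1)^2: minima at z = -1 and z = +1 separated by a
#' barrier of the given height at z = 0. The default barrier/noise pairing
#' (barrier 6, sigma 2.4, so 2 * barrier / sigma^2 ~ 2.1) yields clearly
#' bimodal series that transition between basins several times per simulated
#' decade, emulating bistable elemental profiles.
#'
#' @param barrier Barrier height (> 0).
#' @param sigma Diffusion amplitude.
#' @param z0 Initial state (defaults to the right-hand well).
#' @export
double_well_spec <- function(barrier = 6, sigma = 2.4, z0 = 1) {
  stopifnot(barrier > 0)
  well_spec(c(barrier, 0, -2 * barrier, 0, barrier), sigma, z0)
}

#' Ornstein-Uhlenbeck (mono-stable) specification
#'
#' V(z) = rate * z^2 / 2, i.e. mean reversion toward 0 at the given rate.
#' The default rate of 24 per year corresponds to a relaxation time of about
#' two weeks on the weekly sampling grid, a persistent single attractor.
#'
#' @param rate Mean-reversion rate (> 0, per unit time).
#' @param sigma Diffusion amplitude.
#' @param z0 Initial state.
#' @export
ou_spec <- function(rate = 24, sigma = 1, z0 = 0) {
  stopifnot(rate > 0)
  well_spec(c(0, 0, rate / 2), sigma, z0)
}

#' Specify a regime-switching piecewise sinusoid
#'
#' A deterministic signal with k segments, each a sinusoid with its own
#' frequency, mean, and amplitude, plus i.i.d. Gaussian observation noise.
#' Emulates profiles that move between a high-concentration slow-oscillating
#' state and a low-concentration fast-oscillating state.
#'
#' @param frequencies Cycles per year, one per segment.
#' @param means Segment means.
#' @param amplitudes Segment amplitudes.
#' @param switch_times Strictly increasing switch times (years); k segments
#'   need k - 1 switch times.
#' @param noise_sd Observation noise standard deviation (>= 0).
#' @export
regime_switch_spec <- function(frequencies, means, amplitudes,
                               switch_times = numeric(0), noise_sd = 0) {
  k <- length(frequencies)
  if (length(means) != k || length(amplitudes) != k) {
    stop("`frequencies`, `means`, `amplitudes` must have equal length")
  }
  if (length(switch_times) != k - 1) {
    stop(k, " segments require ", k - 1, " switch times")
  }
  if (k > 1 && any(diff(c(-Inf, switch_times)) <= 0)) {
    stop("`switch_times` must be strictly increasing")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(frequencies = as.numeric(frequencies),
                 means = as.numeric(means),
                 amplitudes = as.numeric(amplitudes),
                 switch_times = as.numeric(switch_times),
                 noise_sd = noise_sd),
            class = "regime_switch_spec")
}

## ---- simulators -------------------------------------------------------------

#' Simulate an overdamped Langevin trajectory
#'
#' Euler-Maruyama integration of dz = -V'(z) dt + sigma dW on a uniform
#' output grid with spacing `dt`. Integration may be refined below the output
#' grid with `substeps` sub-steps per sample; the effective step is
#' dt / substeps. Stability of the explicit scheme requires
#' dt_eff * max|V''(z)| < 2 over the visited range; the simulator checks this
#' on the realized trajectory and warns when violated. Trajectories exceeding
#' `bound` in absolute value abort with an error naming `dt`, the signature
#' of a numerically unstable step size.
#'
#' @param spec A [well_spec()].
#' @param n Number of output samples (>= 10).
#' @param dt Output sampling interval (> 0), also the time unit of the series.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param substeps Integration sub-steps per output sample (>= 1).
#' @param burn_in Output samples to simulate and discard before recording.
#' @param bound Abort threshold on |z|.
#' @return A [biomarker_series()] with time axis `(0:(n-1)) * dt`.
#' @examples
#' dw <- double_well_spec()
#' s <- simulate_langevin(dw, n = 400, dt = 1 / 48, seed = 1, substeps = 8)
#' @export
simulate_langevin <- function(spec, n, dt, seed, substeps = 1, burn_in = 0,
                              bound = 1e6) {
  stopifnot(inherits(spec, "well_spec"))
  if (n < 10) stop("`n` must be >= 10")
  if (dt <= 0) stop("`dt` must be > 0")
  substeps <- max(1L, as.integer(substeps))
  dcoef <- polyderiv(spec$coefficients)
  d2coef <- polyderiv(dcoef)
  h <- dt / substeps
  ntot <- (n + burn_in) * substeps
  dw <- with_seed(seed, stats::rnorm(ntot, 0, sqrt(h)))
  blow <- integer(1)
  z <- .Call(C_langevin_em, as.double(dcoef), as.double(spec$sigma),
             as.double(spec$z0), as.integer(n + burn_in),
             as.integer(substeps), as.double(h), dw, as.double(bound),
             blow)
  if (blow[1] > 0) {
    stop(sprintf(
      "Langevin trajectory exceeded |z| = %g at sample %d: dt = %g is too large for this potential (try more substeps)",
      bound, blow[1], dt))
  }
  z <- z[(burn_in + 1):(burn_in + n)]
  vis <- range(z)
  curv <- max(abs(polyval(d2coef, seq(vis[1], vis[2], length.out = 64))))
  if (h * curv >= 2) {
    warning(sprintf(
      "effective step dt/substeps = %g violates the stability check dt*max|V''| < 2 (max|V''| = %g on the visited range)",
      h, curv))
  }
  biomarker_series((seq_len(n) - 1) * dt, z)
}

#' Simulate a regime-switching sinusoid
#'
#' @param spec A [regime_switch_spec()].
#' @param n Number of samples (>= 10).
#' @param t_max Span of the time axis (years); must exceed the last switch
#'   time. Samples lie on `seq(0, t_max, length.out = n)`.
#' @param seed Integer seed (observation noise).
#' @return A [biomarker_series()].
#' @export
simulate_regime_switch <- function(spec, n, t_max, seed) {
  stopifnot(inherits(spec, "regime_switch_spec"))
  if (n < 10) stop("`n` must be >= 10")
  if (length(spec$switch_times) > 0 && t_max <= max(spec$switch_times)) {
    stop("`t_max` must exceed the last switch time")
  }
  t <- seq(0, t_max, length.out = n)
  seg <- findInterval(t, spec$switch_times) + 1L
  y <- spec$means[seg] +
    spec$amplitudes[seg] * sin(2 * pi * spec$frequencies[seg] * t)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(n, 0, spec$noise_sd))
  }
  biomarker_series(t, y)
}

## ---- generator registry -----------------------------------------------------

# Each generator: function(n, dt, seed, params) -> biomarker_series.
.generators <- list(
  double_well = function(n, dt, seed, params) {
    p <- utils::modifyList(
      list(barrier = 6, sigma = 2.4, z0 = 1, substeps = 8, burn_in = 100), params)
    simulate_langevin(double_well_spec(p$barrier, p$sigma, p$z0), n, dt, seed,
                      substeps = p$substeps, burn_in = p$burn_in)
  },
  ou = function(n, dt, seed, params) {
    p <- utils::modifyList(
      list(rate = 24, sigma = 1, z0 = 0, substeps = 8, burn_in = 100), params)
    simulate_langevin(ou_spec(p$rate, p$sigma, p$z0), n, dt, seed,
                      substeps = p$substeps, burn_in = p$burn_in)
  },
  well = function(n, dt, seed, params) {
    p <- utils::modifyList(
      list(coefficients = NULL, sigma = 1, z0 = 0, substeps = 8,
           burn_in = 100), params)
    simulate_langevin(well_spec(p$coefficients, p$sigma, p$z0), n, dt, seed,
                      substeps = p$substeps, burn_in = p$burn_in)
  },
  regime_switch = function(n, dt, seed, params) {
    p <- utils::modifyList(
      list(frequencies = c(1.2, 4), means = c(2, 0), amplitudes = c(1, 1),
           switch_fracs = 0.45, noise_sd = 0.15), params)
    t_max <- (n - 1) * dt
    sw <- if (length(p$frequencies) > 1) p$switch_fracs * t_max else numeric(0)
    simulate_regime_switch(
      regime_switch_spec(p$frequencies, p$means, p$amplitudes, sw, p$noise_sd),
      n, t_max, seed)
  }
)

#' Available cohort series generators
#' @return Character vector of generator names usable in [cohort_spec()].
#' @export
available_generators <- function() names(.generators)

## ---- cohorts ----------------------------------------------------------------

#' Specify a synthetic case/control cohort
#'
#' @param n_cases,n_controls Group sizes (>= 1).
#' @param generators Named list, one entry per element label; each entry is a
#'   list with components `control` and `case`, themselves lists with a
#'   `generator` name (see [available_generators()]) and any generator
#'   parameters.
#' @param sex_p Bernoulli probability of sex = 1.
#' @param age_mean,age_sd Normal model for the age covariate (years).
#' @param length_range Per-subject series lengths are drawn uniformly from
#'   this integer range (shared across elements within a subject, mimicking
#'   variable developmental windows captured by a single tooth).
#' @param dt Sampling interval in years (default 1/48, roughly weekly).
#' @param seed Cohort seed; all subject- and series-level seeds derive from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, generators,
                        sex_p = 0.5, age_mean = 55, age_sd = 10,
                        length_range = c(300, 600), dt = 1 / 48, seed = 1) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (is.na(n_cases) || n_cases < 1) stop("`n_cases` must be >= 1")
  if (is.na(n_controls) || n_controls < 1) stop("`n_controls` must be >= 1")
  if (length(generators) == 0 || is.null(names(generators)) ||
      any(names(generators) == "")) {
    stop("`generators` must be a named list (one entry per element)")
  }
  for (el in names(generators)) {
    g <- generators[[el]]
    if (!all(c("control", "case") %in% names(g))) {
      stop("element '", el, "' needs a generator for both groups")
    }
    for (grp in c("control", "case")) {
      nm <- g[[grp]]$generator
      if (is.null(nm) || !nm %in% names(.generators)) {
        stop("unknown generator '", nm, "' for element '", el,
             "'; available: ", paste(names(.generators), collapse = ", "))
      }
    }
  }
  stopifnot(length(length_range) == 2, length_range[1] >= 10,
            length_range[2] >= length_range[1], dt > 0)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 elements = names(generators), generators = generators,
                 sex_p = sex_p, age_mean = age_mean, age_sd = age_sd,
                 length_range = as.integer(length_range), dt = dt,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Demonstration cohort with planted case/control differences
#'
#' 36 cases and 31 controls with five elemental pathways. Copper (and, more
#' weakly, lithium) carries a planted state-count difference: bistable
#' double-well dynamics in controls versus mono-stable mean reversion in
#' cases. Magnesium and manganese carry a planted periodicity difference:
#' both groups follow a slow-then-fast regime-switching oscillation, with
#' higher observation noise in cases depressing determinism. Zinc is a null
#' pathway, identical in both groups.
#'
#' @param seed Cohort seed.
#' @param n_cases,n_controls Group sizes.
#' @return A `cohort_spec`.
#' @export
demo_cohort_spec <- function(seed = 1, n_cases = 36, n_controls = 31) {
  rs <- function(noise) list(generator = "regime_switch",
                             noise_sd = noise)
  cohort_spec(
    n_cases = n_cases, n_controls = n_controls,
    generators = list(
      Cu = list(control = list(generator = "double_well"),
                case = list(generator = "ou")),
      Li = list(control = list(generator = "double_well", sigma = 2.0),
                case = list(generator = "ou")),
      Mg = list(control = rs(0.15), case = rs(0.40)),
      Mn = list(control = rs(0.30), case = rs(0.50)),
      Zn = list(control = list(generator = "ou"),
                case = list(generator = "ou"))
    ),
    seed = seed
  )
}

#' Null cohort: identical generators in both groups
#'
#' Used for calibration studies; the default single pathway follows
#' moderately mixing double-well dynamics in both groups so that detected
#' state counts and recurrence features vary across subjects but carry no
#' group signal.
#'
#' @param seed Cohort seed.
#' @param elements Element labels.
#' @param n_cases,n_controls Group sizes.
#' @param length_range Per-subject series length range.
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(seed = 1, elements = "Cu",
                             n_cases = 36, n_controls = 31,
                             length_range = c(300, 450)) {
  g <- list(generator = "double_well", sigma = 1.6)
  gens <- stats::setNames(
    rep(list(list(control = g, case = g)), length(elements)), elements)
  cohort_spec(n_cases, n_controls, gens, length_range = length_range,
              seed = seed)
}

#' Simulate a cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: a list of subjects, each a list with
#'   `subject_id`, `group` ("case"/"control"), `sex`, `age`, and `series` (a
#'   named list of [biomarker_series()], one per element).
#' @examples
#' coh <- simulate_cohort(demo_cohort_spec(seed = 1, n_cases = 3, n_controls = 3))
#' length(coh)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  n_sub <- length(groups)
  covs <- with_seed(spec$seed, {
    list(sex = stats::rbinom(n_sub, 1, spec$sex_p),
         age = round(stats::rnorm(n_sub, spec$age_mean, spec$age_sd), 1),
         len = sample(seq(spec$length_range[1], spec$length_range[2]),
                      n_sub, replace = TRUE))
  })
  subjects <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    grp <- groups[i]
    sid <- sprintf("S%03d", i)
    series <- list()
    for (j in seq_along(spec$elements)) {
      el <- spec$elements[j]
      g <- spec$generators[[el]][[grp]]
      params <- g[setdiff(names(g), "generator")]
      sseed <- (spec$seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      s <- .generators[[g$generator]](covs$len[i], spec$dt, sseed, params)
      s$subject_id <- sid
      s$element <- el
      series[[el]] <- s
    }
    subjects[[i]] <- list(subject_id = sid, group = grp,
                          sex = covs$sex[i], age = covs$age[i],
                          series = series)
  }
  structure(subjects, class = "cohort",
            elements = spec$elements, seed = spec$seed)
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x, `[[`, "", "group")
  cat(sprintf("<cohort> %d subjects (%d cases / %d controls), elements: %s\n",
              length(x), sum(grp == "case"), sum(grp == "control"),
              paste(attr(x, "elements"), collapse = ", ")))
  invisible(x)
}
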