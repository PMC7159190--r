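# attractr

Attractor dynamics and recurrence analysis of longitudinal biomarker time
series.

## What this is for

Some biomarkers can be measured not at a handful of visits but hundreds of
times along a developmental axis — the motivating example is elemental
concentration (metal-to-calcium ion count ratios) profiled along tooth
dentine growth increments, giving ~300–600 roughly weekly samples from
birth through late childhood. Such series carry *dynamical* information:
does the regulatory system occupy one homeostatic state or switch between
several, and how prevalent, long, and complex are its cyclical episodes?
`attractr` extracts these properties per subject and element and carries
them into case/control statistics and disease classification, for
researchers in biomarker epidemiology and developmental exposure biology.

## The methods in brief

**Potential landscapes (stochastic view).** A standardized series z is
modeled as an overdamped gradient system dz = −V′(z)dt + σdW; at
stationarity the Fokker–Planck equation gives

&nbsp;&nbsp;&nbsp;&nbsp;U = −(σ²/2)·log P_d,&nbsp;&nbsp; reported as U/σ² = −log(P_d)/2,

with P_d the Gaussian-kernel density estimate (Scott bandwidth
sd·n^(−1/5)). Local minima of U (on grid regions of non-negligible
density) are quasi-stable states S_L, S_H, …; the maximum between two
minima is the tipping point. The state count n_states is the headline
feature. Rolling 50-sample windows give a time-resolved landscape surface.

**Recurrence quantification (geometric view).** The series is
delay-embedded (Takens) with τ from the first local minimum of the average
mutual information and m from false nearest neighbours. Distances are
thresholded at an adaptive ε fixed to a 10% recurrence rate; from the
diagonal-line histogram P(l):

- Determinism DET = Σ_{l≥lmin} l·P(l) / Σ_{l≥1} l·P(l), lmin = 3
- Mean diagonal length MDL = Σ_{l≥lmin} l·P(l) / Σ_{l≥lmin} P(l)
- Entropy ENT = −Σ_{l≥lmin} p(l)·ln p(l)

**Downstream.** Per element: Poisson regression of n_states and linear
models of DET/MDL/ENT on group + sex + age, with Benjamini–Hochberg FDR
across elements; LASSO-penalized logistic and gradient-boosted tree
classifiers on the dynamical features only, a 60/40 train/test split,
2000-resample bootstrap ROC bands, the threshold maximizing TPR − FPR, a
rank-based test of AUC against chance, and a top-5-feature refit.

Since the motivating human data are not public, the package ships
generators (Langevin double-well / Ornstein–Uhlenbeck, regime-switching
sinusoids, cohort assembly with planted effects) that reproduce the
structure the analysis assumes; see the vignette
(`vignettes/attractor-dynamics.Rmd`) for every default and its rationale.

## Worked example

```r
library(attractr)
cohort   <- simulate_cohort(demo_cohort_spec(seed = 1))  # 36 cases / 31 controls
features <- extract_features(cohort)

subset(compare_groups(features), feature == "n_states")
#>    element  feature    estimate        se        p_raw  flag        p_fdr
#> 1       Cu n_states -0.64376633 0.2075030 1.919305e-03 FALSE 0.0031988418
#> 5       Li n_states -0.49440622 0.2021447 1.445300e-02 FALSE 0.0180662462
#> 9       Mg n_states -0.65340872 0.1701082 1.224664e-04 FALSE 0.0003061661
#> 13      Mn n_states -0.75942130 0.1885121 5.613331e-05 FALSE 0.0002806665
#> 17      Zn n_states -0.02829935 0.2444096 9.078217e-01 FALSE 0.9078216729

classify_cohort(features, seed = 1)
#> <attractor_prediction> train 39 / test 28
#>   lasso AUC 1.000 (1.00-1.00)  acc 100.0% @ 0.499  p = 2.671e-08
#>         top-5 refit AUC 1.000 (1.00-1.00)
#>   gbt   AUC 1.000 (1.00-1.00)  acc 100.0% @ 0.536  p = 1.174e-07
#>         top-5 refit AUC 1.000 (1.00-1.00)
```

The copper state-count rate ratio exp(−0.64) ≈ 0.53 says cases form about
half as many quasi-stable copper states as controls (the planted
mono-stability), surviving FDR; the null zinc pathway shows nothing. Both
classifiers separate the groups essentially perfectly at this planted
effect size; the printed threshold is the point maximizing distance from
the chance diagonal, and p is the rank-test probability of such an AUC
under chance.

Per-series objects have `print`/`plot`/`summary` methods:

```r
s <- cohort[[40]]$series$Cu       # a control subject's copper profile
potential_landscape(s)
#> <potential_landscape> 2 quasi-stable state(s) at -1.08, 0.92; tipping point(s) at -0.13
rqa(s)
#> <rqa> m = 6, tau = 6, eps = 0.968 (rate 0.100, target 0.10)
#>   DET = 0.542  MDL = 4.647  ENT = 1.531 (lmin = 3)
```

A YAML-configured pipeline (`run_all()`, or the thin wrapper in
`inst/cli/attractr.R`) writes series CSVs + manifest, a feature table,
test results, ROC points, JSON summaries, and a provenance log; see
`inst/extdata/demo_config.yaml`.

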