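---
title: "Methods: stacked difference-in-differences PPML for deforestation outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked difference-in-differences PPML for deforestation outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestdid)
```

## The estimation problem

Community land titles (Indonesian social forestry: HD village forests, HKm
community forests, HTR community plantation forests) are granted to areas in
different calendar years. The policy question is whether a title changes the
area's annual deforestation rate — deforested hectares divided by the area's
total hectares. Because titling is staggered and plausibly selective, the
design compares each titled cohort, before and after its titling year,
against candidate areas that the government has designated for future
titling but not yet titled: units drawn from the same administrative
selection process, which is a more credible counterfactual than matching on
observable geography.

### The stacked panel

A *cohort* is the set of areas titled in the same year `g`. For each cohort
we form one sub-experiment: the cohort's treated units plus the control
pool, every unit contributing all panel years (2001–2019, the span of the
annual loss-year record). Sub-experiments are concatenated ("stacked") with
a cohort label. Within a sub-experiment,

* `treat` marks the cohort's treated units,
* `post` marks years `t >= g` (the titling year itself counts as post,
  since a title granted early in the year can bind within it),
* `did = treat x post` carries the treatment effect.

Candidate controls appear in every sub-experiment but are a single cluster
for inference, since standard errors are clustered where treatment is
assigned — the study area.

The default fixed-effect layout (`fe_columns("shared")`) absorbs four
dimensions: study-area effects, year effects, cohort-specific pre/post
effects, and cohort-specific treated/control-group effects. Whether the
area and year effects should additionally be interacted with the cohort is
a genuinely open design choice; `fe_mode = "interacted"` provides that
variant, and the default keeps them shared. The control pool is
candidates-only by default; `control_rule = "not_yet_treated"` additionally
admits units titled after the study window. No covariate matching of
controls is performed: time-varying selection pressure makes the direction
of matching bias unclear, so the design leans on the designated-candidate
pool instead.

### Poisson pseudo-maximum likelihood

The outcome is a non-negative rate with many zeros (most area-years lose no
forest), so the conditional mean is modelled on the log scale and estimated
by Poisson pseudo-maximum likelihood:

`E[y_it | x] = exp(tau * did_it + beta * precip_it + fe_it)`.

PPML is consistent for any non-negative outcome with this conditional mean;
no distributional assumption on the rate is needed. `tau` is interpreted as
the change in the log deforestation rate caused by a title. An equivalent
count formulation passes deforested hectares as the outcome with
`offset = log(total_area_ha)`; it solves a slightly differently weighted
moment condition and is exposed as a supported mode rather than the
default, because the rate is the declared outcome of the design.

Annual precipitation enters standardized — `(x - mean) / sd` with the
population (`n`) denominator — computed once per estimation sample after
stacking, exactly as it would be on real merged CHIRPS records.

## The fitting engine

`fit_ppml()` runs iteratively reweighted least squares. The fixed effects
are never materialized as dummy columns: each IRLS step demeans the working
response and covariates within every fixed-effect dimension by weighted
alternating projections (a compiled kernel with Irons–Tuck extrapolation of
the sweep map). By Frisch–Waugh logic the coefficients from the absorbed
regression equal those of the full dummy regression; the test suite checks
this equality against an explicit-dummy `glm()` fit to 1e-6.

Numerical choices:

* **Convergence**: relative deviance change below `1e-8` *and* maximum
  coefficient change below `1e-7`. The inner projection tolerance is `1e-8`,
  relaxed to `1e-6` while the outer iteration is still far from its optimum.
* **Starting values**: coefficients at zero, the linear predictor at
  `log((y + group mean)/2)` using the first fixed-effect dimension's group
  means — near the group-mean initialization that makes Poisson IRLS
  dependable, and guarded against zeros. Because this start is
  quasi-saturated, deviance-based step-halving only engages from the second
  iteration, once the iterate lies in the model space.
* **Separation**: a fixed-effect group whose outcome is identically zero is
  perfectly fit by a group effect of minus infinity; its rows carry no
  information about the covariates. They are dropped before estimation,
  iterating across dimensions until stable, and reported as
  `n_dropped_separated` — never silently.
* **Collinearity**: covariates that become collinear after demeaning are
  detected by pivoted QR and dropped with a message.

### Cluster-robust inference

The variance is the sandwich on the absorbed design,
`V = A^-1 (sum_c s_c s_c') A^-1`, with `A = X~' W X~` the expected
information for the covariates after profiling out the fixed effects and
`s_c` the within-cluster sum of scores `(y_i - mu_i) x~_i`. A `G/(G-1)`
small-sample factor is applied by default (`G` clusters); the full
Stata-style `(N-1)/(N-k)` correction is deliberately not used, and the
factor can be switched off in `cluster_vcov()`. Confidence intervals are
symmetric Wald intervals on the log scale. With every observation its own
cluster the estimator reduces to the usual heteroskedasticity-robust
variance up to the small-sample factor, which the tests verify.

## What the synthetic laboratory emulates

`sim_scenario()`/`simulate_panel()` draw deforested hectares as
`Poisson(area_i * exp(b0 + a_i + g_t + beta * precip_it + tau_g * D_it))`:
the exact conditional-mean structure the estimator assumes, with log-normal
polygon sizes (median 70 ha, matching the scale of real titled areas), unit
effects of standard deviation 0.5, a mild oscillating year pattern, and
i.i.d. standard-normal precipitation that is re-standardized downstream the
same way real data would be. Defaults: a 1% baseline annual rate and a
precipitation effect of -0.15 on the log scale.

`preset_scenario()` plants, per title-type x forest-class cell, the effect
sizes a real analysis of this policy reports (e.g. +0.14 for HD areas over
all forest, -0.83 for HTR areas on degraded forest), with higher baseline
rates for HTR (plantation-zone areas start from roughly double the
forest-loss rate) and a stronger precipitation effect in primary forest.
These presets let the whole pipeline be exercised against known truths.

`simulate_landscape()` renders the same law as a raster world: each area
becomes a rectangle of 0.09-ha pixels; a still-forested pixel clears in
year `t` with the area's model-implied annual hazard, at most once
(loss-year encoding: 0 = never, k = cleared in 2000+k). The generator
records the loss counts it draws, so zonal extraction can be verified
against it exactly. Deliberately *not* emulated: spatial autocorrelation
within and between areas, spillovers, irregular polygon shapes, peatland
dynamics, and cloud/measurement error in the loss record. Passing tests
therefore validate the estimation machinery, not the remote-sensing
pipeline of a real application.

### Zonal extraction

`zonal_annual_loss()` counts, per polygon and year, the pixels whose
loss-year code matches the year, using the pixel-center containment rule —
chosen over area-weighted fractions because it is exactly testable against
brute-force enumeration; an area-weighted mode is out of scope. Geometries
must share the raster's projected, equal-area frame (meters); polygon areas
come from the attribute table when present, else from the shoelace formula.
Forest-class masks (`reclassify_forest()`) restrict the counts to intact
primary or degraded primary forest; the class-code mapping ships as
user-editable configuration (`default_class_mapping()`) with no claimed
fidelity to any particular published encoding. Rasters travel as ESRI ASCII
grids and polygons as GeoJSON — plain-text formats that round-trip exactly.

## The validation experiments

`run_recovery()` repeats simulate → stack → fit over independent
replicates (replicate `r` seeds the generator with `seed + r`) and reports
bias, RMSE, 95% CI coverage and the 5% rejection rate for the treatment
coefficient. The standard laboratory (`lab_scenario()`) uses three cohorts
(2010, 2013, 2016), 15 treated areas each plus 105 candidates, and 200
replicates — sizes at which the Monte-Carlo error of the mean estimate is
about 0.007 on the log scale, small enough to detect material bias while a
full four-effect-size validation completes in a few minutes on one core.

`run_twfe_comparison()` contrasts the stacked estimator with a naive pooled
Poisson two-way fixed-effects fit on the unstacked panel under
heterogeneous per-cohort effects, both judged against the
cohort-size-weighted mean of the planted effects. Two subtleties, both
consequences of estimand analysis rather than implementation:

* With *time-constant* per-cohort effects, the pooled TWFE estimand is a
  convex combination of the cohort effects (the classic sign-perverse
  contamination requires effects that vary with event time, which this
  generator deliberately does not produce). Its failure mode here is that
  the convex weights are variance-driven and can sit far from the
  cohort-size weights the analyst wants — drastically so when one cohort
  sits at the edge of the panel and contributes almost no pre-period
  contrast.
* The stacked design's real advantage is that each sub-experiment is
  clean, so the cohort-specific effects are identified. The stacked arm of
  the comparison therefore fits one `did x cohort` interaction per
  sub-experiment in a single stacked regression and aggregates by cohort
  size: an explicit weighting that targets the declared estimand directly.
  With a single cohort both arms collapse to the same regression and
  coincide exactly.

The shipped heterogeneous design (cohorts 2002 and 2011 with effects +0.8
and -0.8) makes the weighting failure visible: the pooled TWFE is biased by
roughly -0.4 on the log scale while the stacked aggregate is unbiased up to
Monte-Carlo noise.

## Known limitations

* Pixel-center zonal counts can differ from area-weighted extraction on
  polygons whose boundary cuts many pixels; the discrepancy is bounded by
  the boundary-pixel count times the pixel area.
* PPML drop-and-report separation handling changes the estimation sample;
  with very sparse outcomes (tiny areas, low rates) many units can drop,
  and the reported `n_dropped_separated` should be inspected.
* The `G/(G-1)` cluster correction is first-order; with very few clusters
  a wild-cluster bootstrap (out of scope) would be preferable.
* Heterogeneous-effect aggregation weights sub-experiments by treated-unit
  count; alternative estimands (e.g. area-weighted) require re-aggregating
  the cohort-specific coefficients, which `fit_ppml()` exposes.
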