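---
title: "Climate-sensitive top-height curves from Universal Response Functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-sensitive top-height curves from Universal Response Functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climurf)
```

## The problem

Stand-level growth-and-yield models drive their volume projections from a
top-height curve: the height of dominant trees as a function of total age,
indexed by the site index (SI), the top height at 50 years total age. These
curves are climate-blind — they assume the stand grows its whole rotation
under the climate its SI was measured in, and that any seed source performs
identically. Provenance trials show both assumptions fail: populations are
locally adapted to their source climates, and a warming rotation changes
height growth progressively. `climurf` combines the two traditions. A
Universal Response Function (URF) — a regression of common-garden top height
on provenance climate (the genetic effect), site climate (the environmental
effect), and their interaction — is merged into the species top-height
equation, producing a curve that is specific to one population (via its
provenance climate normals) and sensitive to the climate path of one
plantation (via annual site climate). The curves support two applications:
mapping the change in age-50 SI under climate scenarios, and scanning
candidate seed sources for the one expected to grow tallest at a site — the
quantitative basis of assisted migration.

## The model

### Top-height equations

Each species has a four-constant top-height equation of the form

$$HT(SI, a) = SI \cdot
  \frac{1 + \exp\!\big(c_1 + c_2 A(50) + c_3 G(SI) + c_4\sqrt{50}\big)}
       {1 + \exp\!\big(c_1 + c_2 A(a) + c_3 G(SI) + c_4\sqrt{50}\big)},$$

with the white spruce form using $A(a)=\sqrt{\ln(1+a^2)}$, $G(SI)=[\ln SI]^2$
and the lodgepole pine form $A(a)=\sqrt{\ln(1+a)}$, $G(SI)=\ln SI$. The two
forms are implemented exactly as published, per species, with no
harmonisation; note that the $c_4\sqrt{50}$ term is a constant appearing in
both numerator and denominator, so $c_4$ cancels algebraically and is carried
only for fidelity to the printed form. Since numerator and denominator
coincide at $a=50$, $HT(SI,50)=SI$ identically — the algebraic anchor every
other computation relies on. `invert_site_index()` solves $HT(SI,a)=h$ for
$SI$ by Brent root finding on $SI \in [0.05, 80]$ m with absolute tolerance
$10^{-10}$; the bracket is generous (mapped SI values are below 30 m) but
finite, and a height outside the curve family's reach is an error, never a
clamped value. Because every accepted parameter set is validated at load to
induce a strictly increasing curve in both age (1–80) and SI, the root is
unique whenever it exists.

The four constants have no biological interpretation and are not published in
a transcribable form here; the shipped defaults
(`inst/extdata/species_params_synthetic.yaml`) are a *synthetic* calibration
producing realistic monotone sigmoid shapes, clearly labelled as such. Every
algebraic property of the package (reference-age identity, telescoping
increments, inversion round trips, constant-climate equivalence) is
constant-agnostic; operational use requires supplying the jurisdiction's own
constants via `read_species_params()`.

### Trial preparation

Trees flagged dead, crooked, browsed, or diseased are removed before any
estimation — the health flag is an input column, never diagnosed from the
measurements. Population top heights are then estimated per site and
measurement age from a linear mixed model with population as a fixed effect
and block as a random intercept (`lme4`); a singular fit falls back to a
fixed-effect block adjustment with a notice. We fit per site × age rather
than globally: block effects are nested in sites and have no meaning across
them, and per-site fits keep each trial series' design idiosyncrasies (two
blocks of 3×3 squares in one series, five to nine row-plot blocks in others)
out of each other's variance components.

Because trial series were measured at different ages, each site's
population means are converted to a species-wide common age — 16 years for
white spruce, 32 for lodgepole pine — by inverting the top-height equation at
the measured age and evaluating the resulting SI's curve at the common age.
The measurement age nearest the common age is used, one age per site; when
two ages are equidistant the older is taken, because later measurements
integrate more growth signal. Heights measured at the common age itself are
passed through unchanged.

### Climate variables

The registry holds 22 annual climate variables (`climate_variables()`);
degree-day variables relative to 18 °C are deliberately absent as they lack
direct biological interpretation. Before model search, highly correlated
pairs ($|r| > 0.9$, Pearson, computed separately over provenances and over
sites) are pruned: iteratively, the variable in the largest number of
above-threshold pairs is dropped, ties resolved against the variable later in
registry order. The rule is deterministic and idempotent; which member of a
pair to keep is genuinely arbitrary, so determinism is the property we
engineered for. We use the magnitude $|r|$ rather than signed $r$ — a
strongly negatively correlated pair is just as redundant.

Site climate enters the URF as the *lifespan average*: the mean of the
annual values from the planting year through the age of interest. For
projection runs, the sequence of lifespan averages over ages $1..A$ can be
smoothed by an ordinary least-squares fit of $v = c_0 + c_1\ln(\text{age})$
(`smooth_log_regression()`), which removes inter-annual fluctuation while
keeping the long-term trend; the raw path remains available (smoothing off)
for reconstructing the fitting era exactly.

### The URF and its selection

The URF is an exponentiated quadratic: with provenance variables $x_j$ and
site variables $x_t$,

$$HT = \exp\Big(c + \textstyle\sum a_i x_i + \sum b_i x_i^2 +
  \sum_{j,t} d_{jt}\, x_j x_t\Big) + \varepsilon,$$

with every provenance × site cross term and no within-side crosses; with one
variable per side this is the canonical five-coefficient form. As printed,
that canonical form has no intercept; we include one by default (exposed as
`include_intercept`) because without it a zero-climate input forces a height
of exactly 1 m — an artefact of the parameterisation, not biology.

Model search is exhaustive: all subsets of 1–3 provenance and 1–3 site
variables (e.g. 390,677 candidates for pools of 14 and 17; 53,361 for 11 and
11), partitioned into the nine (|prov|, |site|) categories. Each candidate is
screened by OLS on $\ln(HT)$ — the error in the equation above is additive on
the height scale, but hundreds of thousands of nonlinear fits are not a
defensible screening device, so the log-linear fit serves as the screening
objective, with $R^2$ computed on the original height scale from
back-transformed predictions (an explicit, documented deviation; an optional
Gauss–Newton refinement on the original scale, initialised at the screening
estimates, is available for the finalists and falls back to the screening
estimates if it fails to improve the original-scale SSE). The best fit per
category by original-scale $R^2$ advances to ten-fold cross-validation;
prediction efficiency $EF = 1 - \sum(Y-\hat Y)^2/\sum(Y-\bar Y)^2$ and
$RMSEP = \sqrt{\sum(Y-\hat Y)^2/n}$ are computed on the pooled out-of-fold
predictions, and the candidate with the lowest RMSEP wins (ties: higher EF,
then enumeration order — every tie in the package resolves by deterministic
enumeration order). Folds are assigned uniformly at random over
population × site observations under a fixed seed (default 20240513), keyed
to a stable (site, population) sort so that row order of the input table
cannot change the result. Leave-site-out CV would test spatial transfer more
sternly but confounds the comparison across categories when site counts are
small; random folds are the neutral default and the seed is configurable.

### Merging the URF into the curve

The four-step assembly, per age $i = 1..A$ (default $A = 80$):

1. average the site climate from planting through age $i$ (smoothed if
   requested) and predict the *common-age* top height from the URF under
   (provenance normals, that average);
2. invert the top-height equation at the common age to get $SI_i$;
3. $SI_i$ indexes a static, climate-non-sensitive curve — one per age;
4. take the height at age 1 from the $SI_1$ curve, and for $i \ge 2$ add the
   $SI_i$ curve's increment between ages $i-1$ and $i$ to the running total.

The defining correctness property is the constant-climate limit: if the
climate never changes, all $SI_i$ coincide and the sum telescopes exactly
($10^{-9}$ m in the tests) back to the static curve. We take $H(1)$ from the
$SI_1$ curve rather than from the URF directly: the URF predicts common-age
height, not age-1 height, and the retained-first-value convention keeps step
4 uniform. A falling $SI_i$ path can in principle produce a negative
increment; cumulative height cannot shrink, so increments are floored at zero
with a warning — a documented extension, since the source method never
addresses a collapsing SI path.

### Deployment

`map_local_si()` treats each grid point's own 1961–1990 normals as the local
population's provenance climate and builds its curve under a scenario series
and under a constant replay of the normals; the age-50 difference is the
mapped climate-change impact. `select_optimal_population()` scans candidate
provenance climates (by default 100 points sampled from the in-range grid
under a fixed seed, the count a pure efficiency choice) through full curve
assembly — the per-age interaction terms mean candidate rankings are not
simply rankings of single URF predictions — and returns the maximiser.
Records whose optimal-population SI exceeds 25 m (strictly) are flagged, not
deleted: such values arise where projected climates leave the envelope the
trials sampled, and the flag marks the extrapolation risk. The grid is
consumed as a point table; no resampling or cartography is implemented.

## What the synthetic generator emulates — and what it does not

`make_climate_landscape()` draws points over an Alberta-like box with
latitudinal climate gradients (or independent fields, for identifiability
studies), point-level noise, and annual series with optional linear warming.
`make_trial_dataset()` pushes a known true URF through the species curve to
per-age expected heights, then adds multiplicative lognormal tree noise
(matching the log-scale screening model; an additive mode exercises the
refinement path), additive block shifts, and Bernoulli health flags.
`standardized_true_urf()` states ground truths on standardized climate
scales so effect sizes are comparable across variables with wildly different
units.

This emulates the statistical structure of multi-site, multi-population,
blocked trials, but not: spatially autocorrelated measurement error,
survival/competition feedbacks, age-varying genetic responses, non-linear
warming paths, or the messy age structure of real trial networks. Passing
the recovery tests therefore shows the estimator is consistent and the
pipeline faithful under its own assumptions — it does not validate the URF's
functional form against real forests.

## Numerical choices and problem sizes

* Root finding: Brent, bracket [0.05, 80] m, tolerance $10^{-10}$ on SI.
* Screening OLS via `lm.fit`; rank-deficient designs are flagged collinear
  and excluded from selection rather than silently pseudo-inverted.
* Degenerate data (all heights equal) define $R^2 = 0$ by convention.
* All generators are pure functions of (config, seed); RNG state is saved
  and restored around every seeded operation.
* The test and acceptance runs use deliberately compact problem sizes chosen
  to exercise every code path at full statistical fidelity: landscapes of
  10–45 points, 25 sites × 20 populations (≈500 observations) for recovery
  studies, 20 seeds for selection consistency, 50 replicates for coefficient
  bias, 80-age curves, and 12-point deployment grids with 12 candidates.

## Limitations

The shipped species constants are synthetic (see above). The URF assumes the
climate response of a population is age-invariant — the merging procedure
varies the *climate*, not the response surface, with age. Height is the only
modelled dimension; volume, density, and diameter subsystems of stand-level
models are out of scope, as are downscaling and scenario construction
(climates are consumed as tables). The exhaustive search's statistics are
in-sample for category winners; only the cross-validated RMSEP/EF of the
nine finalists should be quoted.
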