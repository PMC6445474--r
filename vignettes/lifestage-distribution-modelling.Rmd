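---
title: "Life-stage distribution modelling: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-stage distribution modelling: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagedist)
```

`stagedist` models where the life stages of a demersal fish concentrate,
from bottom-trawl survey catches and environmental layers. This vignette
is the package's account of the science: the models, the assumptions
behind them, the tunable parameters, what the synthetic data generator
does and does not emulate, and the numerical decisions a maintainer would
want spelled out.

## From catches to stage CPUE

Two surveys with different gears and tow durations sample the study
extent (3°W–10°W, 52°N–59°N): a 30-minute GOV trawl in the north and
west, and a 60-minute rockhopper trawl in the Irish Sea. Counts are made
comparable by standardising to a 30-minute tow, rounding *down* to whole
fish (`standardise_cpue()`); the floor matters for sparse catches and is
part of the method's definition, not a convenience.

A haul's length-frequency records say how many fish of each 1-cm class
were caught, but not their stage. Stage membership is modelled from
individual sex-maturity-age-length keys (SMALKs) as a binomial GLM with
logit link per stage and survey — length, sex, region (nine named areas
partitioning the extent) and year as candidates, plus survey-specific
pairwise interactions. Backward elimination drops, one at a time, the
removable term with the largest likelihood-ratio-test p-value above 0.05
(a conventional level; the selection rule itself, not the level, is the
method). Marginality is enforced: a main effect is never removed while an
interaction containing it survives. The mature-stage model trains on all
fish of age ≥ 1, with the maturity flag as outcome. Autumn surveys inform
the age-0 model, spring surveys the age-1 and maturity models — a fish
spawned in spring is "age-0" in October and "age-1" by the following
February, so the seasonal split is integral to the stage definitions.

L50 — the length at which the stage probability crosses 0.5 — is the
root of the linear predictor for a fixed sex/region/year profile. Because
the predictor is linear in length whatever interactions survive, it is
computed exactly from its values at two lengths; profiles whose effective
length slope is numerically zero are reported missing rather than
extrapolated.

Stage CPUE per haul is the sum over 1-cm classes of the standardised
count times the predicted stage probability at the class midpoint (lower
bound + 0.5 cm). Length records are often unsexed; those counts use a
sex-averaged probability weighted by the SMALK sex ratio in the same 1-cm
bin, falling back to 0.5/0.5 where no key fish exist. This averaging is a
package decision (the alternative — sexed length records — is rare in
practice) and is recorded in the output metadata.

## Environmental covariates

Covariates enter at the haul position by nearest-cell lookup: depth,
slope, aspect, proximity to shore, sediment class, and year/season-matched
near-bottom temperature and salinity. Hauls on land, rock, or off-grid
are reported and dropped, not imputed — the surveys avoid untrawlable
ground, so such hauls indicate georeferencing noise rather than data.

* **Terrain.** Horn's third-order finite differences on the 3×3
  neighbourhood, the de-facto standard and analytically testable: on a
  plane the operator is exact, which the test suite exploits. Slope is
  `atan` of the gradient magnitude (radians); aspect is the compass
  direction of increasing depth — the downslope direction of the seabed —
  with flat cells assigned 0 by convention and counted.
* **Shore distance.** Distance from each sea-cell centre to the nearest
  coastal land cell minus half a cell width, so a sea cell hugging the
  coast is half a cell from shore. Planar kilometres are used on the
  small synthetic grids; a haversine mode exists for real extents.
* **Sediment.** A mapping table merges 17 raw substratum codes into 5
  habitat-aligned classes; rock is masked out of every modelling layer.
* **CTD surfaces.** Per station×year×season the record with the highest
  pressure (deepest, closest to bottom) is kept; ties keep the last
  occurrence and are flagged. Temperature and salinity surfaces are
  Nadaraya–Watson estimates with Gaussian weights
  `exp(-d²/(2θ²))`, distances in km. The kernel's parameterisation is
  recorded in the layer metadata so an alternative convention can be
  swapped without ambiguity. The bandwidth θ is chosen by *exact*
  leave-one-out cross-validation — removing cast *i* and predicting at
  its position is algebraically identical to a fresh smooth without it,
  and a test asserts as much — on a log-spaced grid (default 8 points,
  5–500 km). A grid, rather than continuous optimisation, keeps the
  selection reproducible and monotonically verifiable; ties take the
  smaller θ, and co-located degenerate casts fall back, flagged, to the
  mid-grid value. For pure-noise fields the expected LOOCV score
  decreases monotonically in θ, but every domain-scale bandwidth at the
  top of a log grid produces a near-identical smoother, so the selected θ
  lands in the top of the grid rather than deterministically at its
  endpoint; the tests assert effectively-maximal smoothing accordingly.

## The hurdle GAMM

Trawl counts are zero-inflated: whether whiting are present at all and
how many are caught where present are driven by different processes. The
package therefore fits a zero-altered Poisson (ZAP) pair per stage:

* a **binomial GAM** on presence/absence of the stage CPUE over all
  hauls, and
* a **zero-truncated Poisson GAM** on the positive hauls, with the CPUE
  rounded to whole fish (floored at 1; the count model's support starts
  at one fish).

Both components share the covariate table and are penalized additive
models: cubic regression splines (basis size 10 by default), tensor
products for two-covariate interactions (5×5), a cyclic cubic spline for
aspect (period 360°, basis 8 — predictions at 0° and 360° are identical
by construction), parametric factors for sediment and year, and a gear
(survey) random intercept realised as a ridge-penalized two-level factor.
With two gear levels a variance component is not meaningfully
identified — gear co-varies with vessel and region anyway — so the
package reports the level contrast and its standard error
(`re_contrast()`) rather than a variance.

The zero-truncated Poisson deserves its own fitter because no installed
GAM machinery provides it as a penalized-smooth family. The family is an
exponential family in canonical form: score `y − μ(η)` and Fisher weight
`μ(1 + λ − μ)` with `μ = λ/(1 − e^(−λ))`, so penalized IRLS applies
unchanged. The engine builds bases and penalties with `mgcv::smoothCon()`
and, at each IRLS step, hands the working penalized least-squares problem
to `mgcv::magic()`, which optimises all smoothing parameters jointly by
GCV (performance iteration). The binomial component runs through the same
engine for uniformity; on shared data its fits agree with `mgcv::gam()`
to correlation 1, and the ZTP component agrees with `glmmTMB`'s truncated
Poisson on parametric models to four decimals — both checked in the test
suite as independent oracles.

Numerical choices worth recording: the GCV denominator uses an effective
degrees-of-freedom inflation of γ = 1.4, the standard guard against
GCV's tendency to undersmooth at survey sample sizes; the linear
predictor is clamped (±30 binomial, ±15 ZTP) before exponentiation; the
normal-equations solve escalates through ridge levels if a smoothing
extreme makes the system numerically singular; and the ZTP saturated
likelihood (needed for deviances) solves `μ(λ) = y` by root-finding on
`[y − 1, y]`, with the `y = 1` supremum of 0 taken analytically.

Model structure is handled in two layers. `vif_screen()` removes
continuous covariates with variance-inflation factor above 3 before any
fitting (screen-then-select; the screening/selection order is logged).
`stepwise_aic()` then runs bidirectional selection from the full
candidate set — drop any current term or re-add any dropped one, take the
move with the lowest AIC (−2ℓ + 2·edf), ties to fewer terms, stop at a
local minimum. One calibration point is worth stating plainly: with AIC,
a pure-noise smooth that shrinks to ~1 effective degree of freedom is
retained with probability ≈ 0.16 by construction, so null terms are
dropped in the clear majority of replicates but not nearly always; the
test suite pins this behaviour to `mgcv`'s own AIC decisions on identical
data rather than to an idealised elimination rate.

Term importance mirrors the usual reporting layout: single-term-deletion
refits at the selected smoothing parameters, with the deviance increase,
the term's edf, and a chi-square p-value.

Prediction surfaces are computed at the population level of the gear
effect (random-intercept columns zeroed; per-gear surfaces available),
with the combined expectation `p · λ/(1 − e^(−λ))` — the correct ZAP
mean; the plain `p·λ` alternative is a switch because "binomial ×
Poisson" is ambiguous between the two and the difference matters at small
λ. Cells outside the training covariate envelope are flagged in an
extrapolation layer rather than silently trusted.

## Aggregation curves, thresholds, persistence

Ranking occupied units (cells of the predicted surface by default; hauls
as an alternative mode) by density from maximum to minimum and
accumulating abundance against area yields a curve from (0,0) to (1,1)
that is monotone, concave up to ties, and lies above the diagonal. The
point where its tangent has slope 1 separates *aggregated* space use
(extra abundance costs little extra area) from *dispersed*. Two
operationalisations are provided:

* **cubic** (default): least-squares cubic on the curve's transition
  phase — the points whose local central-difference slope lies in
  [1/3, 3], a window chosen to bracket slope 1 and widened symmetrically
  to at least four points when the curve is steep; the tangency solves a
  quadratic, keeping the root on the concave branch in [0, 1];
* **empirical**: the first ranked unit whose segment slope falls below 1.

For equal-area units the segment slope equals density divided by the mean
occupied density, so slope 1 is exactly the mean-density crossing — the
module's primary oracle: on random grids the threshold density lands
within a few percent of the occupied-cell mean, and the whole
construction is invariant to rescaling the densities. Uniform surfaces
have no interior tangent; they are flagged degenerate and everything is
classified dispersed. Ties in density never split between classes
(the threshold takes the upper neighbour's density).

Cells above the threshold score 1 per year; summing across years gives
persistence, bounded by the number of years in each seasonal design. The
precision metric reports the percentage of occupied cells whose
cumulative-abundance position lies outside a ±0.025 band around the
threshold's position. One geometric consequence is worth knowing: at the
tangency the curve's slope is ~1, so on a smooth density surface the band
contains ≈ 2 × 0.025 of the cells and precision sits near 95%; values
well above that indicate a density distribution with few cells near the
threshold (strong aggregation), which is exactly how the metric
discriminates.

## Validation

Cross-validation resamples at the haul level — all records of a haul stay
together — with the presence/absence classes kept at the 7:3 ratio to
within one haul each (largest-remainder allocation). Per iteration both
components are refit on the training hauls (smoothing parameters
re-selected by default; a freeze option exists) and scored on the test
hauls: ROC AUC by the rank formula for presence, Spearman correlation on
positive hauls for the count component, and Spearman including zeros for
the combined prediction. Failed refits are logged and excluded, with more
than 20% failures aborting the run. The reference design uses 100
iterations; the pipeline default uses 20 at desk scale.

## The synthetic survey: what it does and does not emulate

Every stage of the pipeline is testable because the generator draws data
from the same model families the estimators assume, with the truth
exported (`export_truth()`).

* **Environment**: a westward-deepening bathymetry with an eastern
  coastline, terrain and shore-distance layers derived by the package's
  own operators, spatially autocorrelated sediment (rock rare), and
  per-year/season temperature and salinity fields. Random fields are a
  fixed low-order trend plus seeded Gaussian noise passed through a
  Gaussian blur — deterministic, fast, and smooth, at the cost of
  oceanographic realism (no fronts, no advection, no realistic coastline
  geometry).
* **Surveys**: 35 GOV (30-min) and 30 rockhopper (60-min) hauls per year
  by default — about 200 hauls per seasonal data set over three years,
  a deliberate desk-scale echo of the real surveys' coverage — placed
  cell-uniformly over each survey's sub-extent with a half-cell margin so
  jitter cannot cross the survey boundary.
* **Stage schedules**: logistic in length with negative slopes for age-0
  and age-1 (smaller fish are the younger ones) and a positive slope for
  maturity; L50 varies by region (±2 cm across the nine regions), sex
  (±0.7 cm) and year (±0.5 cm sinusoid). Autumn fish carry an age-0 label
  drawn at the true logistic; spring fish are all age ≥ 1 with age-1 and
  maturity labels drawn at theirs. Each fitted stage model is therefore
  exactly well-specified — deliberately so, because the L50 recovery test
  is meant to measure estimation error, not model misspecification.
* **Catches**: per haul and season-appropriate stage, presence is
  Bernoulli at `logit⁻¹(η_p + a_gear)` and the positive total
  zero-truncated Poisson at `exp(η_λ + a'_gear)`, with smooth stage-
  specific covariate effects (age-0 shallow and warm-dome; age-1 a 60-m
  depth dome with an aspect term; mature deep) and fixed gear intercepts
  (0 and −0.5 in both components — with two levels only the contrast is
  estimable, so truth fixes it). Totals spread over 1-cm classes by
  truncated-normal stage length distributions — (15, 3), (22, 4),
  (30, 6) cm — overlapping enough that the CPUE decomposition is
  non-trivial. A `null = TRUE` variant zeroes every effect for AUC
  calibration.

Passing tests on these data show the estimators recover a
correctly-specified ZAP process with smooth covariate effects at survey
sample sizes. They do not show robustness to overdispersion beyond
Poisson, spatial residual correlation, preferential sampling, or
misspecified stage schedules — all real-data risks outside the generator
by design (the non-goals of the analysis).

## Problem sizes and determinism

Default desk-scale sizes, chosen to keep a full run comfortably
interactive: a 20×30 grid (the full-resolution study grid is 928×1660
cells of 1.54 km²; the classes carry any shape), ~200 hauls per seasonal
data set over 3 years per season, 120 SMALK fish per region×year, 50 CTD
stations per surface, 20 CV iterations, spline bases trimmed to 8/4×4/6.
Recovery tests use 2000 SMALK fish per region and 1000 hauls. The entire
pipeline is a pure function of (configuration, seed): sub-seeds are
derived additively from the master seed, no parallelism or
time-dependent state is used, and repeated runs produce byte-identical
output files — asserted in the acceptance suite.

## Known limitations

* The count component is Poisson-truncated; field data often need a
  negative-binomial hurdle, which is out of scope here.
* Smoothing selection is GCV-based (γ = 1.4); REML-type selection can be
  less prone to occasional undersmoothing but is not implemented for the
  ZTP family.
* The stage CPUE entering the count model is rounded to whole fish, a
  pragmatic bridge between the probability-weighted decomposition and the
  integer support of the truncated Poisson.
* Region assignment uses rectangular boundaries (point-in-rectangle,
  ties north/west); real survey strata are polygons and would need a
  boundary table.
* Distances are spherical (haversine) at best; no projection support.
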