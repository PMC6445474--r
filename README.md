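# stagedist

Life-stage distribution modelling from bottom-trawl surveys.

Demersal fish such as whiting (*Merlangius merlangus*) change their spatial
distribution over the life cycle: age-0 fish settle in shallow coastal
water, age-1 fish spread along the coast, and mature fish occupy deeper
offshore habitat. Quantifying where each life stage concentrates — and how
persistent those concentrations are across years — is what managers need to
target or avoid specific age classes. `stagedist` implements that analysis
end to end for DATRAS-style survey data (haul records, 1-cm
length-frequency records, sex-maturity-age-length keys) and environmental
grids, and ships a synthetic-survey generator with exported ground truth so
the whole pipeline can be exercised and tested without survey-database
access.

## The method

1. **Life-stage CPUE.** Counts are standardised to a 30-minute tow
   (rounded down to whole fish). The probability that a fish of length
   *l* belongs to a stage (age-0, age-1, mature) is modelled per survey by
   binomial GLMs, logit(p) = α + β₁ sex + β₂ region + β₃ *l* + β₄ year +
   interactions, with backward elimination by likelihood-ratio tests.
   L50 — the length at p = 0.5 — summarises spatial and temporal variation
   in the stage schedules. Stage CPUE per haul is the probability-weighted
   sum over 1-cm length classes.
2. **Environmental covariates.** Terrain derivatives (slope, aspect) from
   bathymetry by Horn's 3×3 operator; distance to shore; a 5-class
   sediment reclassification (rock excluded as untrawlable); near-bottom
   temperature and salinity from the deepest CTD record per station,
   interpolated by a Gaussian kernel smoother whose bandwidth θ is chosen
   by exact leave-one-out cross-validation on a log-spaced grid.
3. **Hurdle GAMM.** A zero-altered Poisson model per stage: a binomial GAM
   for presence and a zero-truncated Poisson GAM for positive CPUE, both
   with penalized cubic regression splines, tensor-product interactions, a
   cyclic spline for aspect, and a ridge-penalized gear (survey) random
   intercept. Collinearity is screened by VIF (> 3 removed); structure
   can be selected by bidirectional stepwise AIC. Expected CPUE combines
   the components as p·λ/(1 − e^(−λ)).
4. **Space-use classification.** Cells (or hauls) ranked by density yield
   a geostatistical aggregation curve — cumulative abundance share versus
   occupied-area share. A cubic fitted to the curve's transition phase
   gives the tangent with slope 1; the density at the tangency is the
   threshold between *aggregated* and *dispersed* cells. Summing the
   per-year binary maps gives persistence; a precision metric reports the
   share of cells outside a ±0.025 band around the threshold.
5. **Validation.** 7:3 train/test splits stratified by haul, repeated;
   ROC AUC for presence, Spearman rank correlation for counts and for the
   combined prediction.

## Worked example

```r
library(stagedist)

# a small synthetic survey with known truth
env    <- generate_environment(1, c(20, 30), years_feb = 2009:2011,
                               years_oct = 2011:2013)
truth  <- truth_spec(years_feb = 2009:2011, years_oct = 2011:2013)
smalks <- generate_smalks(truth, 300, seed = 4)

m <- fit_stage_model(smalks, stage = "AGE1", survey = "SWC_IBTS")
m
#> <stage_model AGE1/SWC_IBTS> n = 5400, retained: sex + region + length + year

compute_l50(m)[1:3, ]
#> # A tibble: 3 x 6
#>   stage survey   sex   region year    l50
#>   <chr> <chr>    <chr> <chr>  <chr> <dbl>
#> 1 AGE1  SWC_IBTS F     Cl     2009   25.1
#> 2 AGE1  SWC_IBTS F     Cl     2010   25.9
#> 3 AGE1  SWC_IBTS F     Cl     2011   25.3
```

The L50 values recover the generator's schedules (the Firth-of-Clyde
female age-1 truth cycles around 25.3 cm across these years). The aggregation threshold on a
toy haul set shows the slope-1 rule:

```r
curve <- build_curve(c(4, 3, 2, 1))      # four equal-area units
tangent_threshold(curve, mode = "empirical")[c("x_star", "y_star", "z_star")]
#> $x_star [1] 0.5   $y_star [1] 0.7   $z_star [1] 2
```

Half the occupied area holds 70% of the fish; units denser than 2 (the
mean-density crossing) are classified aggregated. The full pipeline — from
simulation through persistence maps — is one call:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
res$aggregation$summary[1, c("stage", "year", "z_star", "share_in_20pct_area")]
#>   stage year  z_star share_in_20pct_area
#> 1 AGE0  2011    7.99               0.722
```

On this synthetic design 72% of age-0 abundance sits in 20% of the
occupied area, against 27% for the more dispersed age-1 stage — the
coastal-to-offshore ontogeny the method is built to expose. Every output
(CPUE tables, L50 tables, prediction grids, curves, classified and
persistence grids, CV metrics, a JSON run log) is written as plain
CSV/ASCII-grid files, byte-identical across reruns at a fixed seed.

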