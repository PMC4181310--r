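# fawnsurv

Neonatal ungulates (white-tailed deer, mule deer, pronghorn) are routinely
aged at capture from **new-hoof growth** — the millimetres of hoof grown past
the fetal growth-ring line — using published linear calibrations of the form

```
age (days) = intercept + slope × hoof growth (mm)
```

The estimated age decides the interval at which an animal *enters* a
staggered-entry known-fate survival analysis, so disagreement among
calibration equations (their intercepts range from −8.29 to +5.29 days)
propagates directly into survival estimates — most strongly when mortality is
concentrated in the first weeks of life. `fawnsurv` is a toolkit for studying
that propagation: it is aimed at wildlife biologists and quantitative
ecologists who estimate juvenile survival from radio-telemetry.

It provides:

* a registry of the six published age-from-hoof-growth equations with the
  standard truncation rule (negative predicted ages clamp to a newborn, class
  0 = 0–24 h), accuracy scoring against known-age animals, and summary tables;
* a synthetic cohort simulator (known birth dates, site-structured hoof
  growth, age-dependent two-phase daily mortality, competing collar shedding,
  daily-then-weekly monitoring) so the whole analysis is testable without
  field data;
* construction of staggered-entry encounter histories at daily or weekly
  resolution, with the right-censoring midpoint rule and Program MARK
  known-fate `.inp` import/export;
* maximum-likelihood **known-fate** interval-survival models with logit link:
  the likelihood is a product of simple binomials, one per
  (shared-survival-group × time-block) cell, with arbitrary group-equality
  constraints (`"KA=B=S,H=HS"`), constant/weekly/daily time structures, AICc
  with Akaike weights, and delta-method standard errors for cumulative
  survival `Ŝ(t) = ∏ Ŝ_j`;
* CONTRAST-style chi-square comparisons of survival estimates,
  `χ² = (Ŝ₁ − Ŝ₂)² / (SE₁² + SE₂²)` on 1 df (quadratic-form generalisation
  for k groups);
* a `run_pipeline()` orchestrator that simulates or loads a cohort, builds
  per-equation cohorts, fits every set partition of the cohort labels crossed
  with the time structures, ranks by AICc and contrasts the top model's
  groups.

Everything is tidyverse-native: tibbles in and out, `tidy()`/`glance()` on
fits, `autoplot()` for survival curves.

## Worked example

Age three mule deer fawns from their hoof growth with the Robinette
calibration, then run the full replication pipeline on a simulated cohort of
61 newborns:

```r
library(fawnsurv)

m <- lookup_age_model("mule deer", "Robinette")
estimate_age(m, c(0.82, 3.84, 5.73))
#> # A tibble: 3 × 6
#>   model_name label hoof_growth raw_age truncated_age age_class
#>   <chr>      <chr>       <dbl>   <dbl>         <dbl>     <dbl>
#> 1 Robinette  R            0.82   -4.21          0            0
#> 2 Robinette  R            3.84    3.49          3.49         3
#> 3 Robinette  R            5.73    8.31          8.31         8

cfg <- pipeline_config(species = "mule deer", horizons = 30, seed = 7,
  sim = sim_config(species = "mule deer", n_neonates = 61, seed = 7))
res <- run_pipeline(cfg)
#> pipeline: 61 captured, 61 known-age retained
#> horizon 30: 15 models fitted; KA cohort 31 died, 1 censored

head(res$results[["30"]]$ranking, 5)
#> # A tibble: 5 × 8
#>   model      time_structure  aicc delta_aicc weight     K deviance viable
#>   <chr>      <chr>          <dbl>      <dbl>  <dbl> <int>    <dbl> <lgl>
#> 1 KA = R, H  weekly          441.       0     0.86      7     4.66 TRUE
#> 2 KA, R, H   weekly          445.       3.69  0.136    11     0    FALSE
#> 3 KA, R = H  weekly          452.      11.6   0.003     8    14.2  FALSE
#> 4 KA = R = H weekly          456.      15.6   0         4    26.4  FALSE
#> 5 KA = H, R  weekly          457.      15.7   0         8    18.3  FALSE

res$results[["30"]]$top_survival
#> # A tibble: 2 × 8
#>   group cohorts estimate     se lower upper n_occasions boundary
#> 1     1 KA = R     0.499 0.0453 0.411 0.587           4 FALSE
#> 2     2 H          0.525 0.0639 0.400 0.646           4 TRUE
```

The fawns estimated with a negative hoof growth prediction truncate to age
class 0 (a newborn). The ranking table reads like a MARK model-selection
table: the top model here groups the known-age (`KA`) cohort with the
Robinette (`R`) cohort and lets the Haskell (`H`) cohort differ, on weekly
intervals, carrying 86% of the Akaike weight; its cumulative 30-day survival
estimates (with logit-scale 95% CIs) sit in the last block. The `boundary`
flag notes that one of `H`'s weekly parameters had no deaths and was clamped.
`res$results[["30"]]$contrasts` then tests the two groups against each other
(here χ² = 0.105, 1 df, P = 0.75 — no detectable difference at this sample
size).

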