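# modeshift

Evaluate the effect of moving into a redesigned, walkable, transit-rich
neighbourhood on daily travel behaviour, measured objectively from
time-matched GPS (10-s fixes) and hip-worn accelerometer (10-s count
epochs) streams at two waves.  The package is a complete, tested pipeline
for this class of housing natural experiment:

1. **Synthetic world** — a seeded vector city (street network, land-use
   parcels, parks, stations, PTAL points), a household-structured cohort,
   ground-truth travel diaries, and raw sensor streams; plus a day-level
   generator for statistical recovery studies at full design size.
2. **Sensor ingestion** — GPX/delimited readers, 10-s epoch fusion,
   Troiano-style non-wear detection, and the ≥540-min valid-day rule that
   gates a day's GPS data.
3. **Mode classification** — walking / cycling / motorised vehicle /
   overground train / stationary per epoch, via a deterministic threshold
   rule (the tested oracle) or gradient-boosted trees trained on labelled
   synthetic epochs.
4. **Underground inference** — GPS signal-loss gaps of 2 min–2 h whose
   endpoints are within 200 m of (different) underground stations become
   underground travel minutes.
5. **Built environment** — walkability (z-sum of land-use-mix entropy,
   residential density, street connectivity inside a 1-km network buffer),
   park-entrance network distance, nearest-point PTAL.
6. **Statistics** — residual-adjusted average daily minutes per
   participant-wave, then household-clustered multilevel change models:

   `followup ~ baseline + group + sex + age_group + ethnic_group +
   housing_group + (1 | household)`

   The `group` coefficient estimates the between-group difference in
   within-person change (min/day).  Stratified, weekday/weekend,
   working-subset and 40-imputation (Rubin-pooled) sensitivity analyses
   are included.

## Worked example

Recover a known intervention effect at the published design size (578
participants, ~400 households, housing groups 201/283/94; true effects set
to the published estimates, e.g. vehicle −8.3 min/day):

```r
library(modeshift)

cfg    <- sim_config(seed = 2024, fidelity = "day")
cohort <- generate_cohort(NULL, cfg)
days   <- generate_day_level(cohort, cfg)
summ   <- wave_summaries(days, categories = c("vehicle", "underground_train"),
                         method = "mean")
covs   <- cohort[c("id", "household", "group", "sex", "age_group",
                   "ethnic_group", "housing_group", "working_studying")]

stratified_effects(summ, covs, "vehicle")
#>  outcome      stratum   n estimate              ci       p
#>  vehicle          all 578    -8.63  (-9.65, -7.60) 3.7e-61
#>  vehicle       social 201    -7.97  (-9.77, -6.18) 3.4e-18
#>  vehicle intermediate 283    -9.28 (-10.69, -7.88) 3.8e-38
#>  vehicle  market-rent  94    -8.26 (-11.07, -5.44) 9.2e-09

fit_change_model(summ, covs, "underground_train")
#>            outcome stratum   n estimate           ci       p
#>  underground_train     all 578     4.22 (3.81, 4.63) 1.3e-89
```

One seeded replicate lands near the injected truths (−8.3 vehicle, +3.9
underground); averaged over 200 replicates the recovery is unbiased to
within Monte-Carlo error (see `tests/testthat/test-acceptance.R`).  The
synthetic CIs are narrower than real-cohort CIs because the generator's
day-to-day dispersion is deliberately milder than real, zero-inflated
travel data — see the methods vignette.

Cohort-flow bookkeeping uses exact integer rounding:

```r
cohort_flow(recruited = 1278, followed_up = 877, longitudinal = 578)
#>          stage    n denominator pct
#> 1    recruited 1278        1278 100
#> 2  followed_up  877        1278  69
#> 3 longitudinal  578         877  66
```

An end-to-end epoch-fidelity demo (city → diaries → sensors → fusion →
classification → gaps → exposures → models → tables):

```r
run_pipeline(sim_config(seed = 1, n_participants = 20, n_households = 15,
                        fidelity = "epoch", wear_days = 2),
             out_dir = "demo_out")
```

writes per-stage CSVs, GeoJSON city layers and a JSON manifest with row
counts and content hashes.  A thin CLI wrapper lives at
`inst/cli/modeshift.R`.

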