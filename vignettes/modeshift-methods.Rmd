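---
title: "Methods: evaluating travel-mode change in a housing natural experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating travel-mode change in a housing natural experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(modeshift)
```

## The problem

When a large, purpose-built walkable neighbourhood opens and households move
into it while comparable households do not, the relocation acts as a natural
experiment on the built environment: does living in a dense, mixed-use,
transit-rich district change how people travel day to day?  `modeshift`
implements the full measurement and analysis chain for such an evaluation,
where travel is observed objectively by a hip-worn accelerometer (10-s count
epochs) time-matched to a GPS logger recording position every 10 s, at two
waves roughly two years apart.

Because the underlying cohort's raw data are not publicly deposited, the
package ships a first-class synthetic world with known ground truth.  Every
stage is tested against that truth, and the statistical machinery is
validated by parameter recovery at the published design size (n = 578
participants in ~400 households; housing groups of 201, 283 and 94).

## From sensors to daily minutes

**Fusion and valid days.**  Accelerometer counts and GPS fixes are fused
into half-open 10-s slots aligned to midnight.  Epoch speed is the planar
distance between consecutively attached fixes divided by the inter-fix
time, in a single local projected CRS in metres (longitude/latitude exists
only at the GPX boundary).  Non-wear is a run of ≥60 consecutive zero-count
minutes (Troiano-style; the threshold is config-exposed because the source
protocol does not state one).  A calendar day is *valid* with ≥540 wear
minutes, and a day's GPS data enter the analysis only if its accelerometry
is valid — a valid accelerometer day with no GPS contributes zero-minute
GPS categories rather than being dropped, since the inclusion rule
conditions on accelerometry alone.

**Classification.**  Each worn epoch is assigned to walking, cycling,
motorised vehicle (bus and car are not separable), overground train, or
stationary.  Two classifiers share one feature set (window median and 95th
percentile speed, acceleration, epoch and window counts, distance to the
nearest rail line, fix availability):

* a deterministic threshold rule — stationary below 0.2 m/s; 0.2–2 m/s is
  walking when counts clear a walking floor; 2–7 m/s is cycling when counts
  clear a cycling floor; above 7 m/s is overground train within a 50-m rail
  corridor, vehicle otherwise.  One extra guard is needed beyond the speed
  bands: GPS positional noise gives a genuinely stationary device an
  apparent 0.3–0.7 m/s, so sub-walking speeds with near-sedentary counts
  are stationary, not slow vehicle travel;
* a multinomial gradient-boosted tree model trained on labelled synthetic
  epochs (500 rounds, depth 3, learning rate 0.05 by default).  No boosted
  tree library is available in the target environment, so a compact
  softmax boosting implementation with exact-greedy regression trees is
  included.  The rule classifier is retained as the independent oracle: on
  zero-noise synthetic data it recovers ≥99 % of true labels, and the two
  classifiers agree on ≥95 % of epochs.

Short label runs (<30 s) are absorbed into their longer neighbour,
earliest-first and earlier-neighbour on ties, iterated to a fixed point —
which makes the smoother deterministic and idempotent.

**Underground travel** is never classified from epochs (no signal
underground); it is inferred from signal-loss gaps.  A gap — a fixless run
bounded by fixes on both sides while worn — is underground when its
duration is between 2 min and 2 h (inclusive) and its endpoints satisfy the
station condition.  The source describes two endpoint conditions (either
endpoint near a station; both endpoints near two *different* stations); both
are implemented behind a switch with the stricter, twice-stated version as
default.  Epochs inside a flagged gap are re-assigned from stationary to
underground so no minute is counted twice.

## Built-environment exposures

All exposures are computed in a 1-km street-network buffer around the home
address (snapped to the nearest street edge, 100-m tolerance; partial edges
cut at exactly the radius; the buffer polygon is the reachable edges
dilated by 25 m — both the dilation width and parcel-intersection rule are
package choices, the source being silent):

* **land-use mix**: −Σ pᵢ ln pᵢ / ln 5 over the five classes' floor-area
  shares (0 = single use, 1 = perfectly even);
* **residential density**: residential units per km² of residential parcel
  land, in thousands;
* **street connectivity**: street nodes of degree ≥3 within the buffer per
  km of reachable road;
* **walkability**: the sum of the three components' z-scores.  The
  reference population is the baseline cohort, and the baseline means/SDs
  are frozen and reused at follow-up, so a change in walkability reflects a
  change in environment rather than a drifting reference;
* **park distance**: shortest network distance to the nearest entrance of
  any park (three classes), including the perpendicular access leg;
* **PTAL**: the score of the Euclidean-nearest public-transport
  accessibility sample point (ties to the lowest point id).  Whether the
  source used network or Euclidean proximity is unstated; Euclidean is the
  default and the operation is switch-ready.

Network operations are validated against independent Floyd–Warshall
oracles on random ≤50-node graphs.

## Perception scores and covariates

Fourteen 4-point neighbourhood-perception items are factor-analysed at
baseline (maximum likelihood, two factors, promax rotation).  Factors are
named by the item group carrying the dominant loading mass, oriented so
higher = safer/better, and scored by the regression method (weights
R⁻¹Λ); baseline weights and item standardisation are frozen and applied to
follow-up responses.  Up to two missing items are imputed at the baseline
item mean; more yields a missing score.  One caveat documented here
because it fails a naive expectation: with oblique factors the regression
weights contain small negative cross-loadings, so the respondent answering
"best" on every item is near, but not exactly at, the score maximum.

Covariate coding follows the UK conventions: ages 16–24/25–34/35–49/50+,
"Mixed" ethnicity merged into "Other", NS-SEC three classes plus an
economically-inactive class that includes students, the retired, home
carers and those unable to work.

## The statistical model

**Residual-adjusted daily averages.**  Per wave and category, daily minutes
are modelled with day-order, day-of-week and month as fixed effects and a
participant random intercept.  A participant's summary is the grand
population mean plus the mean of their residuals from the fixed-effects
prediction.  "Population mean" is defined here as the mean fixed-effects
prediction over all observed days, which makes the cohort mean of the
adjusted estimates equal the population mean exactly.  Constant factors
(e.g. month in a one-week window) are dropped; a singular mixed fit falls
back to the fixed-effects model with a warning; negative estimates are
floored at zero with a logged count (the source does not say whether it
floored).

**Change model.**  Follow-up average daily minutes are regressed on the
baseline average, East Village/Control group, sex, age group, ethnic group
and housing group, with a household random intercept (REML; Wald 95 % CIs
— the source names neither the estimator nor the interval type).  The group
coefficient is the effect of moving.  Stratified fits drop the housing
covariate; weekday-only/weekend-only analyses re-summarise the day
profiles before refitting; the working/studying-at-baseline subset is a row
filter.  Missing follow-up outcomes can be multiply imputed (m = 40
default) from a proper Bayesian linear imputation model on the same
covariates, with Rubin's rules for pooling — chosen because the source
names only the imputation command, and Rubin pooling is its standard
companion.  With no missing data the pooled fit equals the complete-case
fit exactly, which the tests assert to machine precision.

## The synthetic world: what it emulates, and what it does not

The generator has two fidelities.

**Epoch fidelity** builds a rectilinear grid city (200-m blocks) with
parcels, parks with street-node entrances, underground/overground stations,
an offset rail corridor, and a denser, mixed-use, station-rich "East
Village" district in one corner; a cohort of households (quota-allocated to
housing groups and mover status so the realised design matches 201/283/94
and the published mover fractions exactly); contiguous daily episode
diaries whose routes follow shortest network paths; and raw sensor streams
— 10-s fixes with Gaussian positional noise (5 m default), suppressed with
probability 1 underground and 0.5 indoors, plus lognormal mode-specific
count distributions.  Two deliberate departures from naive realism are
documented in the ledger: the rail line runs 60 m off the road grid
(otherwise road traffic is inside the rail corridor and the
vehicle/overground distinction is unlearnable even noiselessly), and
underground trips are book-ended by short station-access walks so the
bounding fixes actually lie near stations.

**Day fidelity** bypasses sensors for statistical recovery at full n: per
participant-wave-day minutes are `category mean + household + household×wave
+ person + day noise + (group × wave) effect`, truncated at zero.  Category
means default to the published all-housing Control baseline values (summing
to 552 min of daily GPS time); true effects default to the published
change estimates, with a stratum-specific 3×6 matrix available.  Noise
levels are CVs of the category mean — 0.10 household, 0.08 household×wave,
0.20 person, 0.20 day-to-day — chosen a priori so the truncated-Gaussian
model keeps the stated means within 1 %.  Two consequences are worth
stating plainly:

* the generator's dispersion is *below* the real cohort's (real
  minutes-per-day are zero-inflated and right-skewed; a Gaussian matching
  the printed SDs would truncate heavily and shift the means).  Synthetic
  CIs are therefore narrower than published ones, and a green recovery test
  establishes estimator correctness, not real-world power;
* the household×wave component is not in the minimal three-component noise
  menu.  It is included because households relocate as a unit, and without
  household-level change variance the analysis model's household intercept
  is degenerate (variance ~0) on most replicates — the prescribed model
  would be permanently in its singular-fallback branch.

Truncation at zero makes the raw injected effect slightly attenuated; the
effect-injection test therefore checks the empirical group difference in
change against the exact truncated-normal expectation, and additionally
that for the five travel modes this expectation is within 0.05 min/day of
the configured effect.  For `stationary` at its default −247 min effect the
truncation distortion is ≈4 min (1.6 %) — real, acknowledged, and outside
every acceptance target.

## Numerical and procedural choices

* All distance bounds are inclusive ("within 200 m" ⇒ ≤200; 2 min ≤ gap ≤
  2 h).
* Percentages in flow/descriptive tables round half away from zero to
  integers, matching the presentation convention.
* Ties: PTAL → lowest point id; label smoothing → earlier neighbour;
  boosted-tree argmax → first class.
* Seeds: every generator consumes `seed + stage offset` under
  `withr::with_seed`, so identical configurations are byte-identical and
  stages are independently reproducible.
* Degenerate inputs error early with actionable messages (unsnappable
  address reports the nearest-edge distance; unknown covariate categories
  are listed; single-class training data, <2 households, single-group
  strata are refused or skipped with warnings).

## Known limitations

* The boosted-tree stand-in is not the published classifier; its
  validation statistics transfer only to the synthetic world.
* The city is rectilinear with one district; there is no routing realism
  beyond shortest paths, no clock drift, no multi-city support (all
  declared non-goals).
* PTAL is an assigned nearest-point score; computing it from timetables is
  out of scope.
* Indoor signal loss is a single Bernoulli dropout; the real phenomenon
  (high-rise shadowing concentrated in the intervention district, which the
  source discusses at length) is not modelled, so the large published
  stationary/total-time artefacts are reproduced only through their
  injected day-level effects.
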