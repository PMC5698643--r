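---
title: "Methods: climate, phenology and grouse breeding success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate, phenology and grouse breeding success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tetrao` implements the analysis chain of a long-term two-species grouse
study as reusable, tested components. This vignette is the package's own
account of the science: the models and their assumptions, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the decisions taken where the design was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The study system and the question

Capercaillie and black grouse are large, mono-brooding, lekking
tetraonids of the boreal forest. Females mate at leks in late April,
incubate for about four weeks, and hatch precocial chicks in early June
whose survival depends on weather and on caterpillar food in bilberry
vegetation. The mismatch hypothesis predicts that warmer springs advance
mating and push hatching out of synchrony with peak food, depressing
reproduction. Testing this needs four data streams — daily weather,
August brood surveys, predator/prey covariates, and lek mating dates —
and a battery of trend and climate-window regressions connecting them.

## Weather-derived phenology

All weather enters as one station series of daily minimum, average and
maximum temperature, precipitation and an ordinal snow-cover score (0–5).
Temperatures are transferred to the study site by a lapse rate
(`lapse_rate`, default 0.65 °C per 100 m; `elevation_diff` is site minus
station in metres, so a site above the station is colder).

Three onset indicators are derived per year, scanning 1 January–30 June:

* **Snow-free date**: earliest day with score ≤ `snow_free_score`
  (default 0, i.e. under 20 % cover). First occurrence wins even if snow
  returns later — the definition is "the earliest date".
* **Frost-free date**: the centre day of the first `ma_window`-day
  (default 7, must be odd) window whose mean daily minimum exceeds 0 °C.
  The moving average is *centred*: symmetric smoothing is the standard
  reading for phenological indicators, and the first upward crossing is
  used without any persistence requirement, because the indicator is
  defined by the crossing alone. If the earliest computable window is
  already positive, its centre day is returned. Whether a trailing
  average was ever intended is unknowable from the definition; the
  centred choice is documented here precisely because it is a choice.
* **GDD threshold date**: growing degree days accumulate as
  `max(t_avg − gdd_base, 0)` per day with `gdd_base = 5` °C from
  `gdd_start` (default 1 January), and the onset of summer is the first
  day the cumulative sum reaches `gdd_threshold = 200`. Accumulation from
  1 January is a convention, not a claim: winter days contribute
  essentially nothing under the base-5 clamp, which is exactly why the
  simple convention is safe. The daily *average* is used, the
  conventional degree-day input.

Monthly means (April–June) and the mean over any closed day-of-year
window complete the weather module. The "13 successive periods" of the
breeding season default to thirteen 7-day windows tiling 1 April–30 June
(13 × 7 = 91 days), the natural exact tiling of the season.

**Missing-data policy.** Derived dates propagate `NA` (no crossing, never
reaching the threshold); window and monthly means refuse to average over
gaps and fail with the gap count instead. Silent partial means would bias
trend estimates in exactly the years most likely to have broken records.

## Breeding phenology and windows

Only capercaillie mating peaks are observed. Hatch is mating +
`mating_to_hatch_cap` days and incubation starts `incubation_length_cap`
days before hatch. The interspecific lags are fixed at +5 (mating), +8
(incubation start) and +6 days (hatch) for black grouse. The
mating-to-hatch interval itself is not published for this system, so the
default 38 days with 26 days of incubation (hence 12 of laying) was
chosen to be consistent with late-April mating, early-June hatching and
the published lags; both numbers are configurable and everything
downstream shifts rigidly with them (translation equivariance is a tested
property).

Missing mating years are imputed from the ordinary linear trend of the
observed dates (not carried forward) and flagged, so inference can drop
them. Two observed years are the mathematical minimum for that line and
are accepted; with so few observations the imputation is of course only a
placeholder, and the flag is the mechanism for excluding it.

The four analysis windows are closed day ranges: `pre8` =
[hatch−56, hatch−1], `pre_inc4` = [incubation−28, incubation−1], `inc` =
[incubation, hatch−1], `post4` = [hatch, hatch+27]. "Four weeks" is
exactly 28 days, the incubation window ends the day before hatch, and
`pre_inc4`/`inc` partition the tail of `pre8` whenever incubation ≤ 28
days.

## Survey metrics

August dog-survey records carry, per block: effort hours, lone females,
and the chick counts of each brood. Records are pooled within
species-year *before* ratios are formed (ratio of sums, not mean of
ratios) because the analysis wants one annual value and blocks are
unequal-effort subsamples. Females = lone females + brooded females;
August counts cannot separate non-breeders from failed breeders, which is
a documented property of the index, not something the package models.
Encounter rates are birds per 10 h of pooled effort. The identity
`breeding_success = brood_frequency × brood_size` holds exactly by
construction whenever at least one brood was seen, and is verified to
1e-12 across every simulated species-year in the test suite.

## The statistical battery

* **Trends**: OLS of each annual series on calendar year; slope β with
  its standard error, Pearson r, two-sided p, and the total change
  Δ = β × span. The span is the *inclusive* year count (a 1979–2016
  study spans 38 years): this convention — not span − 1 — is what turns a
  slope of 0.050 °C/yr into the 1.9 °C April rise, and the acceptance
  suite checks all five such conversions.
* **AR-error comparison**: the same trend model refitted by maximum
  likelihood with independent, AR(1) and AR(2) errors (`nlme::gls`),
  compared by AIC. Low autocorrelation shows up as the independent model
  winning or tying, which is the justification for reporting plain OLS.
  Non-convergence of an AR fit is reported per model, never fatal.
* **Normalized β** = β / series mean: a scale-free relative trend, the
  only way to compare a proportion's trend with a count's.
* **Log-ratio trend**: OLS of log(A/B) on year tests whether two series'
  *proportional* trends differ; non-positive years are dropped loudly.
* **Slope difference**: t = (β₁−β₂)/√(se₁²+se₂²) with Welch–Satterthwaite
  degrees of freedom from the two residual dfs — the df formula is not
  dictated by the original reporting (only t and p are), and Welch is the
  standard choice for unequal variances.
* **Window regressions**: each demographic index on each window's mean
  minimum temperature (minimum temperature is the designated predictor:
  it has the smallest year-to-year variation and correlated best with
  breeding success in the source system).
* **Partial regressions**: the index on temperature plus √rodents and
  log fox. β_p is the multiple-regression temperature coefficient; r_p is
  the correlation of the two covariate-residual series. By Frisch–Waugh
  the residual-on-residual slope *is* β_p, and the package exposes both
  routes so the equivalence is testable (it holds to 1e-10 on random
  instances in the acceptance suite). Zero fox indices are shifted by
  half the smallest positive value before the log, with a warning; a
  condition-number guard (κ > 1e8) flags near-singular designs.
* **Lagged tests**: the index on mean June–August daily average
  temperature 1 and 2 years earlier. "Summer" is not defined more finely
  by the source; June–August is the meteorological convention.
* Two-sided p throughout, α = 0.05 with a 0.05–0.10 "near-significant"
  band in the reporting conventions; **no multiple-testing correction**,
  matching how such long-term single-population batteries are reported —
  users comparing many windows should treat isolated p ≈ 0.04 entries
  accordingly.

## Mismatch analysis

The offset is hatch date minus the GDD₅ = 200 date, negative when
hatching runs early. Breeding success is regressed on the offset with
polynomials of order 1 and 2; the winner is chosen by AICc — with ~40
annual points and 2–3 parameters the small-sample correction is the
appropriate form of AIC — and the order-2 optimum −b₁/(2b₂) is reported
when the curvature is negative. The overall p is the F-test against the
intercept-only model. Imputed-phenology years are retained in the points
(their flag travels with the phenology table for users who prefer to drop
them).

## The synthetic-data generator

`sim_config()` / `sim_study()` generate all four input streams with the
statistical structure the analysis assumes. Defaults are the study
conditions; every parameter is configurable.

**Weather.** Daily mean temperature is a seasonal sinusoid (site mean
2.5 °C, amplitude 13.7 °C, peak day 201 — chosen so April/May/June means
sit near the source system's monthly climatology) plus month-specific
linear warming, shared AR(1) daily noise (φ = 0.6, innovation sd 1.6),
a shared month-level anomaly (sd 1.2 °C) and small independent
per-variable noise (sd 0.4). Minimum and maximum ride at −4.5/+5.5 °C
around the mean and the ordering `t_min ≤ t_avg ≤ t_max` is enforced.
The warming slopes default to the published monthly values for April
(0.050/0.069/0.101 °C/yr for min/avg/max), May (0.052/0.019/0.012) and
June (0.047/0.022/0.024), with a modest 0.03 elsewhere. The month-level
anomaly is the load-bearing noise term: daily AR(1) alone would give
window means an interannual sd near 0.8 °C, while the published
year-to-year standard errors imply ≈ 1.2–2.0 °C; one shared draw per
year × month (persistent circulation regimes) restores that spread.
Precipitation is a wet-day gamma process and snow cover a degree-day
snow pack (accumulate precipitation on days ≤ 0.5 °C, melt at
5 mm per positive degree-day) mapped to the 0–5 score.

**Covariates.** The rodent index is a sinusoidal cycle (period 3.5 yr,
amplitude 2.2 around base 3 — the 3–4-year vole cycle) with a random
phase, plus 0.22 index units per °C of same-year June–August mean, plus
noise; fox follows lag-1 rodents at 0.078 with noise; both floored just
above zero. The two coupling coefficients are recovered by the package's
own regressions in expectation (tested over replicate series).

**Mating dates.** Baseline day 121 (late April) advancing at
−0.12 day/yr, plus a weak coupling (0.15) to the *detrended* frost-free
anomaly — detrended so that a cold late spring delays mating without
silently altering the configured long-term trend — plus 2 days of noise,
rounded to whole days.

**Breeding.** Each female broods with a logit-link probability and each
brood's chicks are the binomial survivors of a hatched clutch
(1 + Binomial(clutch − 1, q), clutch 8), floored at one chick because an
August "brood" is by definition a female with surviving chicks. The
clutch-survival form was chosen over a truncated Poisson because real
brood counts are underdispersed relative to Poisson, and the resulting
signal-to-noise of the window regressions (realized |r| ≈ 0.35–0.4 at 38
years) matches the magnitude of correlation such studies report. Effect
sizes are specified on the *linear* scale of the pipeline's regressions
(slope of the index per °C) and converted internally to the link scales
at the baseline — a first-order match, documented, not claimed exact:
brood frequency responds to the 8-week pre-hatch minimum temperature at
0.049 per °C in capercaillie and 0 in black grouse (the published
interspecific contrast), both species' brood size responds to the 4-week
post-hatch minimum at 0.136/0.138 per °C, and brood frequency responds
to rodents at 0.03 per index unit (unpublished in the source; a modest
value consistent with the small attenuation its partial regressions
show). Baselines: brood probability 0.45/0.55, brood size 4.3, mean
females per year 18/22 — sized so total birds per year fall inside the
published 112–186 range. Birds are scattered over 10 of 25 sampling
blocks with uniform 8–15 h effort.

**Scenario configurations used by the validation suite.** Two
configurations besides the defaults are exercised, at 38 years × 200
replicates each:

* *Null*: all breeding effects (temperature *and* rodent) set to zero.
  The rodent pathway must be off too — rodents are coupled to summer
  temperature, so with the rodent effect active a zero temperature
  coefficient is a confounded hypothesis, not a null. Under this
  configuration the window regression's type-I error is checked against
  its nominal 5 %.
* *Mismatch*: a log-scale quadratic penalty on expected brood size,
  `mismatch_gamma` = 0.007 per squared day of offset (≈ 50 % chick loss
  at 10 days of mismatch, the magnitude reported for strongly
  food-limited passerine systems), with all temperature/rodent breeding
  effects off. Isolation is essential, not cosmetic: post-hatch warmth
  and the offset are positively correlated through the shared GDD date
  (a warm June pulls GDD₅ = 200 earlier and pushes the offset up), so an
  active post-hatch temperature effect displaces the realized success
  peak away from zero offset and the premise "survival peaks at offset
  0" fails before any fitting starts. The default configuration keeps
  `mismatch_gamma = 0`, matching a system whose breeding effects act
  through temperature windows.

**What the generator does not emulate.** No spatial block geography or
double-count process (records are born deduplicated); no
individual-based predators; no carry-over of breeding success into
next-year abundance; observation effort is uniform rather than
survey-shaped; and onset-date *trends* are emergent consequences of the
monthly temperature trends rather than targets — the generator pins the
temperature structure, so its snow-free/frost-free advances are smaller
than the three weeks the real system showed, which likely reflects
finer-than-monthly structure in real early-spring warming. Passing tests
therefore demonstrate that the estimators recover what the generator
encodes at realistic noise levels — not that the generator reproduces
every marginal statistic of the field system.

## Numerical choices

* Dates are (year, day-of-year), 1-based, windows closed on both ends;
  leap years are handled through real calendar dates.
* The frost-free crossing uses a 1e-9 °C tolerance above zero so that an
  exactly-zero window mean (constructible with symmetric inputs) is not
  promoted to "positive" by floating-point summation.
* Perfect-fit regressions (zero residual variance) report r = ±1 and
  p = 0 rather than NaN; zero-variance responses are flagged, with β = 0.
* AICc = AIC + 2k(k+1)/(n−k−1) with k the full parameter count including
  the residual variance.
* Degenerate designs error early: all-equal offsets, zero pooled
  standard errors with unequal slopes, windows reaching before day 1.

## Problem sizes

The validation suite runs the full pipeline at the study's own scale —
38 years, two species, ~150 birds per year — with 200 replicates for the
sign-recovery, type-I and mismatch checks, 100 random instances for the
Frisch–Waugh and GDD brute-force equivalences, and 300–500 replicates
for the cheaper scalar simulations. These sizes give Monte-Carlo
standard errors comfortably below the margins being asserted.

## Known limitations

* Window regressions treat annual index estimates as homoskedastic
  observations; years with fewer females are noisier than the OLS
  weights assume (the source reporting does the same).
* The logit/log scale-matching of generator effects is first-order, so
  recovered coefficients are expected to sit within a few percent of the
  configured linear values, not exactly on them.
* Imputed mating years re-enter every downstream analysis unless the
  user filters on the `imputed` flag.
* The AR comparison addresses temporal autocorrelation only; no spatial
  error structure is fitted.
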