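# tetrao

Climate–phenology–demography analysis for boreal forest grouse.

`tetrao` packages the complete analysis pipeline of a long-term
(multi-decade) study of sympatric capercaillie (*Tetrao urogallus*) and
black grouse (*Tetrao tetrix*): from raw daily weather series and August
pointing-dog brood surveys to the statistical battery that asks whether
warmer springs help or hurt grouse reproduction. It is aimed at
quantitative ecologists running or re-analysing climate-window studies of
bird breeding success.

## What it computes

**Phenology from daily weather.** Station temperatures are transferred to
the study site with a lapse rate (default 0.65 °C / 100 m), then three
onset indicators are derived per year:

- *snow-free date* — earliest day with snow-cover score 0 (< 20 % cover on
  the 0–5 scale);
- *frost-free date* — first day the centred 7-day moving average of daily
  minimum temperature exceeds 0 °C;
- *onset of summer* — the day cumulative growing degree days above 5 °C
  reach GDD₅ = 200 (completed bilberry shoot growth in this system).

**Breeding windows.** Capercaillie mating peaks anchor hatch
(mating + 38 d) and incubation start (hatch − 26 d); black grouse trail by
+5/+8/+6 days (mating / incubation / hatch). Four closed windows are
realized per species-year: 8 weeks pre-hatching, its 4-week pre-incubation
and incubation parts, and 4 weeks post-hatching.

**Demographic indices.** Survey records pooled per species-year give
breeding success *BS* (chicks per female), brood frequency *BF*
(proportion of females with ≥ 1 chick) and brood size *B* (chicks per
brood), with the exact identity *BS = BF × B* whenever broods were seen.

**The regression battery.** OLS year-trends β with total change
Δ = β × span; GLS refits with AR(1)/AR(2) errors compared by AIC;
normalized (β / mean) and log-ratio interspecific comparisons; window
regressions of each index on window mean minimum temperature; partial
regressions controlling for √rodents and log fox (partial r via
residual-on-residual regression, equal to the multiple-regression
coefficient by Frisch–Waugh); slope-difference t tests with
Welch–Satterthwaite df; lagged June–August temperature tests.

**Mismatch analysis.** Per species-year offset = hatch date − GDD₅ = 200
date (negative = hatching early); order-1 vs order-2 polynomial response
of breeding success on the offset, selected by AICc, with the quadratic
optimum −b₁/(2b₂) reported.

**Synthetic study generator.** `sim_study()` emulates the whole system —
month-specific warming (strongest in April), AR(1) + monthly-anomaly
weather noise, a degree-day snow pack, 3–4-year rodent cycles coupled to
summer temperature, fox lagged one year behind rodents, a weak mating-date
advance, and clutch-survival breeding responses — so every stage of the
pipeline runs, and its estimators can be validated, without field data.

## Worked example

```r
library(tetrao)

# a reproducible 38-year synthetic study (weather, surveys, covariates, mating)
study <- sim_study(seed = 1)

# demographic indices from the August surveys
indices <- demographic_indices(study$survey)
indices[indices$species == "capercaillie", ][1:3, 1:5]
#>    year species      breeding_success brood_frequency brood_size
#> 1  1979 capercaillie             3.04           0.667       4.56
#> 2  1980 capercaillie             1.64           0.318       5.14
#> 3  1981 capercaillie             1.5            0.45        3.33

# brood frequency vs 8-week pre-hatch minimum temperature
tab  <- analysis_table(study$weather, study$phenology, indices, study$covariates)
capt <- tab[tab$species == "capercaillie", ]
temp_response(capt, brood_frequency, t_pre8)
#>   response        predictor     n   beta     se     r       p
#> 1 brood_frequency t_pre8       38 0.0584 0.0207 0.425 0.00785
partial_regression(capt, brood_frequency, t_pre8)
#>   response        predictor controls            n beta_partial     se r_partial       p
#> 1 brood_frequency t_pre8    rodent_sqrt+fox_log 38       0.0554 0.0199     0.431 0.00867

# hatch-date mismatch analysis
pts <- compute_offsets(study$phenology, study$onsets, indices)
select_mismatch_model(pts[pts$species == "capercaillie", ])
#> Mismatch model selection (AICc): order 1 selected
#>  order  n r.squared  p.value  aicc optimum_offset selected
#>      1 38    0.1976 0.005174 79.64             NA     TRUE
#>      2 38    0.2043 0.018314 81.82             NA    FALSE
```

Read: in this simulated study, capercaillie brood frequency rises by
0.058 per °C of pre-hatch minimum temperature (r = 0.43, p = 0.008), and
barely changes after adjusting for rodents and fox (β_p = 0.055) — the
temperature effect is not a predator-cycle artefact. With the default
configuration breeding effects act through temperature, so the mismatch
selection settles on the linear response.

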