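# partmig

Seasonal survival analysis for partially migratory populations: who pays
for winter, and what would it take for the other strategy to break even?

In a partially migratory bird population, some individuals migrate for the
winter and some stay. If migrants survive winter better, residency can
only persist if it buys breeding benefits. Testing this requires
estimating **seasonal apparent survival** (Φ) separately for migrants and
residents from presence–absence monitoring in which **detection** (P) is
imperfect — and an order of magnitude lower for migrants, who are absent
from the monitored site for half the year. `partmig` implements the whole
analysis chain for this design and a synthetic-data generator that
emulates it, so every stage is testable without field data.

## What is inside

* **Hidden-Markov capture–recapture engine** (`fit_cmr()`,
  `hmm_loglik()`): conditional-on-first-capture two-state (alive/dead)
  forward-algorithm likelihood with additive logit-linear effects of
  season type, migratory strategy, sex and age on Φ and of strategy or
  season on P; BFGS multistart, observed-information covariance,
  back-transformed Wald intervals (`predict_rates()`). An independent
  closed-form Cormack–Jolly–Seber oracle (`cjs_loglik_oracle()`) and a
  generic finite-state `forward_loglik()` back it up in the tests.
* **Model language and selection** (`parse_model_spec()`, `qaicc()`,
  `rank_models()`): model strings such as `Phi[season+migr].P[migr]`,
  QAICc = deviance/ĉ + 2K + 2K(K+1)/(n_eff − K − 1), criterion
  differences Δi and Akaike weights ωi.
* **Data preparation** (`build_season_calendar()`,
  `classify_strategies()`, `apply_exclusion_filters()`,
  `build_encounter_matrix()`): alternating summer/winter occasion
  calendars, migratory-strategy classification from dated detection and
  nocturnal-departure records, the exclusion filters (undetermined,
  winter departers, switchers, unsexed juveniles), and the
  individuals × occasions 0/1 matrix.
* **Break-even fitness** (`expected_reproductive_seasons()`,
  `breakeven_excess()`): expected lifetime number of reproductive seasons
  `s1 + s1·s2/(1 − s1·s2)` (winter survival `s1`, summer survival `s2`;
  first breeding needs one winter, each further breeding one more
  summer–winter cycle) and the percentage by which resident breeding
  success must exceed migrants' for equal strategy fitness.
* **Synthetic cohorts** (`simulation_config()`, `simulate_population()`,
  `simulate_detection_records()`) and an orchestrated, deterministic
  pipeline (`run_pipeline()`).

## Worked example

Simulate a cohort with the default study design (192 residents, 70
migrants, 15 seasonal occasions 2009–2016; winter survival 0.57
residents / 0.73 migrants, resident summer survival 0.89, detection
0.74 / 0.19), fit the generating model, and look at the seasonal rates:

```r
library(partmig)

cfg <- simulation_config(seed = 20260921)
pop <- simulate_population(cfg)
fit <- fit_cmr("Phi[season+migr].P[migr]", pop$history, pop$covariates)

rbind(
  winter_resident = predict_rates(fit, list(season = "winter")),
  winter_migrant  = predict_rates(fit, list(season = "winter",
                                            strategy = "migrant")),
  p_resident      = predict_rates(fit, list(strategy = "resident"),
                                  type = "p"),
  p_migrant       = predict_rates(fit, list(strategy = "migrant"),
                                  type = "p"))
#>                 estimate     lower     upper   se_link
#> winter_resident 0.5928840 0.5269402 0.6556427 0.1367554
#> winter_migrant  0.7813630 0.6634433 0.8662936 0.3035518
#> p_resident      0.7434854 0.6923246 0.7887351 0.1291627
#> p_migrant       0.2074054 0.1530999 0.2747249 0.1887054
```

At this (realistic, modest) sample size the estimates straddle their
generating values: migrants survive winter markedly better than
residents, and are far harder to detect. The break-even calculation turns
seasonal survival into expected reproductive seasons:

```r
e_m <- expected_reproductive_seasons(0.73, 0.89)   # 2.584695...
e_r <- expected_reproductive_seasons(0.57, 0.89)   # 1.599633...
breakeven_excess(e_m, e_r, rounding = 2)           # 61.25
breakeven_excess(e_m, e_r)                         # 61.58
```

So with those seasonal rates, a migrant can expect about 2.58 breeding
seasons against a resident's 1.60, and residents would need roughly 61%
higher breeding success to reach equal fitness; 61.25% is the value from
expectancies quoted at two decimals, 61.58% the full-precision one.

## Analysis workflow

The numbered drivers under `analysis/` run the study end to end and
write their tables under `results/`:

| script | stage |
|---|---|
| `01_simulate_cohort.R` | draw the synthetic cohort and its dated record stream |
| `02_prepare_histories.R` | classify strategies, apply exclusions, build the encounter matrix (and verify it round-trips the generator's) |
| `03_fit_candidate_models.R` | fit the 15-model candidate set on the generator and prepared matrices |
| `04_model_selection.R` | QAICc tables with Δi and Akaike weights |
| `05_breakeven_fitness.R` | expectancies, break-even excess, sensitivity surface |

On the default seed the data-generating structure
`Phi[season+migr].P[migr]` tops both tables (weight ≈ 0.7), and the
side-by-side fits show the classification-conditioning selection effect
discussed in the vignette (`vignettes/partial-migration-survival.Rmd`).

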