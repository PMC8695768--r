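# xylodyn

Analysis of intra-annual wood formation (xylogenesis) from repeated
micro-core cell counts. `xylodyn` is aimed at tree-ring and forest-growth
researchers who monitor cambial activity through a growing season — counting
cambial, enlarging, wall-thickening and mature cells on successive
micro-cores — and want a reproducible pipeline from raw per-tree counts to
growth kinetics, phenology and a rate-versus-duration decomposition.

## The model

Cumulative wood cell production of tree *i* in a stand is modelled by a
Gompertz curve with a tree-level random asymptote:

    Y_ij = (A + a_i) · exp(−exp(β − k · t_ij)) + ε_ij,
    a_i ~ N(0, σ_A²),   ε_ij ~ N(0, σ_e²)

where *t* is the day of year, *A* the population asymptote (final cell
number), *β* the time-placement parameter and *k* the rate parameter.
Estimation is restricted maximum likelihood via `nlme`. From the fitted
parameters the package derives the standard kinetic quantities:

- inflection date `t_p = β/k` (day of the fastest growth),
- maximal rate `r_max = kA/e` (cells/day),
- average rate over the 5–95 % development window,
  `r_m ≈ (9/40)·e·r_max ≈ 0.6116·r_max` (an exact window-quotient form,
  `0.9A/(t95−t5) ≈ 0.6015·r_max`, is also exposed),
- the window bounds `t5`, `t95` from the closed-form quantile inversion.

Phenology follows the enlargement-phase rule (onset = first sampling day
with an enlarging cell, end = last such day, duration = end − onset), and
within-season bimodal extrema of cambial/enlarging trajectories are found
by prominence-filtered peak detection on loess-smoothed series. Final cell
number is decomposed into rate and duration contributions by OLS
(`Y = α0 + α1·rate + α2·duration`) with an LMG relative-importance
allocation of the model's R².

A synthetic-data module generates realistic multi-phase count trajectories
(two-pulse production, residence-time phase structure, Poisson noise,
tree-level asymptote heterogeneity, dormancy gating of the growing window)
so every stage is testable without field data.

## Worked example

```r
library(xylodyn)

# five-age-class study: 5 stands x 5 trees, 33 micro-core collections each
study <- generate_study(paper_scenarios(), seed = 1)
nrow(study)
#> [1] 825

fit <- fit_stand(dplyr::filter(study, stand_id == "2012"))
fit
#> Gompertz stand fit (nlme, REML on 'total' counts)
#>   stand: 2012
#>   A = 197.1 (SE 14.7), beta = 2.183 (SE 0.0856), k = 0.01059 (SE 0.000632)
#>   sigma_A = 26.96, sigma_e = 8.541, R^2 = 0.928, n = 165 (df 162)

kinetic_summary(fit$fixed)
#> # A tibble: 1 × 6
#>     t_p r_max   r_m    t5   t95 r_m_method
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <chr>
#> 1  206. 0.768 0.470  102.  486. approx
```

(The fitted asymptote sits below the scenario's population parameter
because the simulated growing window closes before the curve plateaus —
the estimate describes the season actually realised, as it would for
field data.)

`t_p` is the day of year of fastest growth, `r_max` and `r_m` the maximal
and average production rates in cells/day. An end-to-end run produces the
full report bundle:

```r
res <- run_study(study_config(scenarios = paper_scenarios(), seed = 1))
res$importance
#> # A tibble: 2 × 4
#>   predictor   lmg lmg_normalized percent
#>   <chr>     <dbl>          <dbl>   <dbl>
#> 1 rate      0.871          0.891    89.1
#> 2 duration  0.107          0.109    10.9
```

i.e. in this simulated study most of the between-tree variance in final
cell number is attributable to the rate, not the duration, of wood cell
formation — the typical pattern where rates vary strongly across ages
while growing-season length varies little.

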