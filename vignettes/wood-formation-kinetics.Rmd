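---
title: "Modelling intra-annual wood cell development with xylodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling intra-annual wood cell development with xylodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylodyn)
library(dplyr)
```

`xylodyn` analyses repeated micro-core observations of wood formation: for
each monitored tree and sampling day, the counts of cambial, enlarging,
wall-thickening and mature cells (three radial rows averaged per slice, so
row-averaged counts are integers after rounding). This vignette explains
the models and rules the package implements, the design decisions behind
them, and what the simulation-backed tests do and do not demonstrate.

## The growth model and its kinetics

Cumulative cell number over a growing season is modelled by the Gompertz
curve

$$Y(t) = A \exp(-\exp(\beta - k t)),$$

an asymmetric sigmoid with asymptote $A$ (final cell number), placement
$\beta$ and rate $k$ (per day). Its useful closed forms are implemented in
`gompertz_value()`, `gompertz_rate()`, `inflection_point()` ($t_p =
\beta/k$, where $Y = A/e$), `max_rate()` ($r_{max} = kA/e$) and
`quantile_time()` ($t_q = (\beta - \log(-\log q))/k$). The 5–95 %
development window $[t_5, t_{95}]$ has length $\log(\log 20 / \log(20/19))
/ k \approx 4.0674/k$, independent of $\beta$.

Two conventions exist for the average rate over that window. The exact
window quotient is

$$r_m = \frac{0.95A - 0.05A}{t_{95} - t_5} \approx 0.6015\, r_{max},$$

while the kinetics tables conventionally use the compact approximation

$$r_m \approx \tfrac{9}{40} e\, r_{max} \approx 0.6116\, r_{max}.$$

Both are exposed (`mean_rate(p, method = )`, `rm_from_rmax()`); the
approximation is the default because it reproduces published two-decimal
$(r_{max}, r_m)$ pairs for stands of every age class, and the two differ
by under 1.7 % relative for any parameters. Which convention produced any
particular published table cannot generally be determined from rounded
values, which is precisely why both paths are implemented.

## Mixed-effects estimation

`fit_stand()` estimates

$$Y_{ij} = (A + a_i)\exp(-\exp(\beta - k t_{ij})) + \varepsilon_{ij},
\qquad a_i \sim N(0, \sigma_A^2),\ \varepsilon_{ij} \sim N(0, \sigma_e^2)$$

with tree $i$ as the random factor acting on the asymptote — trees in a
stand share timing and rate shape but differ in how many cells they
ultimately produce. Estimation uses `nlme::nlme()` with restricted maximum
likelihood by default (`method = "ml"` available). Design choices:

- **Initialisation** is deterministic: $A_0 = 1.05 \times$ the maximum
  observed count, then OLS on the linearisation
  $\log(-\log(Y/A_0)) = \beta - k t$ restricted to interior points
  ($0.05 A_0 < Y < 0.95 A_0$). This removes seed sensitivity and gives
  reliable convergence; up to three multiplicatively jittered restarts are
  tried before falling back.
- **Fallbacks**: with fewer than two trees, or if every mixed fit fails,
  the model degrades to fixed-effects nonlinear least squares
  (`minpack.lm::nlsLM`) with $\sigma_A = 0$ and a warning; the `converged`
  flag is honest.
- **$R^2$** is not uniquely defined for mixed models, so the package
  reports $1 - SSE/SST$ with population-level (fixed-effects-only)
  predictions, clamped to $[0,1]$; a conditional (tree-level) variant is
  available via `compute_r_squared(fit, level = "tree")`.
- **Residual df** is reported as $n_{obs} - 3$ (the three fixed
  parameters), the convention used in per-stand Gompertz reporting.
- Residuals are homoscedastic Gaussian even though counts are integers;
  this follows standard practice for cell-count series of this magnitude
  and keeps the model comparable with the field's published fits. For
  Poisson-like noise the fixed effects remain near-unbiased (the
  recovery simulations confirm 2-SE coverage around 90 %), though the
  reported standard errors do not model the variance–mean scaling.

## Phenology rules

Onset, end and duration of wood cell development are assessed on the
enlargement phase: onset is the first sampling day whose (row-averaged)
enlarging count exceeds zero — at least one row shows an enlarging cell —
and end is the last such day (`detect_onset_end()`, `tree_phenology()`).
Timings are assigned to observed sampling days, never interpolated: field
assessments come from discrete weekly/biweekly collections, and stand
means over integer sampling days naturally produce fractional summary
values. `stand_phenology()` reports per-stand means and sample SDs; by
linearity, mean duration equals mean end minus mean onset exactly. A
single tree gives SD 0 with an explicit `sd_defined = FALSE` flag; an
all-zero series yields a `no_growth` record rather than an error.

## Bimodal extrema

Subtropical and Mediterranean conifers often show two within-season
activity peaks in cambial and enlarging counts, separated by a mid-season
slowdown. `smooth_series()` (loess, degree 1, tricube weights, evaluated
on the observed grid) filters sampling noise; `find_bimodal_extrema()`
then identifies interior local maxima by sign changes of discrete
differences, keeps those with topographic prominence at or above
`min_prominence`, labels the two most prominent — in day-of-year order —
as first/second seasonal maxima, and takes the intervening and following
grid minima. The series' first point is eligible as a boundary maximum
(dormant-season cambial counts typically start at their annual maximum)
and the last point as the final minimum. Defaults: `span = 0.25`,
`min_prominence = 0.5` cells — chosen to resolve seasonal bumps roughly
120 days apart on a 7–10-day sampling grid without chasing count noise;
both are arguments throughout. Ties resolve to the earliest day;
monotone series are flagged `"none"`, single-peak series `"unimodal"`,
and more than two prominent peaks sets `ambiguous = TRUE` while keeping
the two most prominent. A `second_lower` flag records whether the second
maximum is at or below the first (the typical field pattern); it is
reported, not enforced.

Smoothing trades variance for bias: at noise well below the smoothing
bias at sharp peaks, smoothing can *increase* the mean squared deviation
from truth. The package's tests therefore evaluate the smoother at
Poisson-scale noise (SD $\approx \sqrt{\text{peak count}}$), where it
reliably helps.

## Age effects and the rate–duration decomposition

`age_trend_anova()` tests per-tree quantities (final cells, onset, end,
duration, rate-peak day, maximal/average rate) against stand age. The
default enters age as a *numeric* covariate, giving the 1-df
regression-ANOVA line whose $F$ equals the squared slope $t$; this
matches the convention of reporting one df per characteristic across
several age classes. A classical one-way factor ANOVA (df = number of
classes − 1) is available with `mode = "factor"`.

`fit_rate_duration()` fits $Y = \alpha_0 + \alpha_1 x_1 + \alpha_2 x_2$
by OLS, where $Y$ is each tree's final cell count, $x_1$ its production
rate and $x_2$ its growing-season duration. Because the per-tree rate is
not directly observed, the pipeline derives it from the stand fit's
conditional asymptotes: $r_{max,i} = k (A + a_i)/e$, with the average
rate $r_{m,i} = 0.6116\, r_{max,i}$ the default regressor
(`rate_def = "mean"`; `"max"` switches to $r_{max,i}$). Defining the rate
as final cells divided by duration is deliberately excluded — it would
make the decomposition circular.

`lmg_importance()` allocates the regression's $R^2$ among predictors by
the LMG rule: each predictor's share is the average over all predictor
orderings of its incremental $R^2$, computed over subsets with the exact
factorial weights $|S|!\,(p-|S|-1)!/p!$. Shares always sum to the
full-model $R^2$; normalised shares divide by it. Collinear — even
duplicated — predictors are accepted (every subset $R^2$ is a
well-defined projection, and LMG splits shared variance symmetrically);
only a zero-variance predictor or response is rejected. Tests verify the
closed form against brute-force enumeration of orderings to $10^{-10}$.

## The synthetic-data generator

Because raw micro-core tables are rarely deposited, the generator is a
first-class module. It emulates:

- **Two-pulse production.** Cumulative production is a mixture
  $P(t) = a\,[s\,g(t) + (1-s)\,g(t-\Delta)]$ of two Gompertz pulses
  sharing $(\beta, k)$, with split $s$ and offset $\Delta$. A single
  pulse ($s = 1$) is exactly the Gompertz curve. Phase counts follow by
  fixed residence-time differencing: enlarging $= P(t) - P(t - d_e)$,
  wall-thickening the next lag window, mature the fully lagged curve, and
  cambial $=$ baseline $+$ gain $\times dP/dt$. Defaults $d_e = 18$ and
  $d_t = 40$ days place the wall-thickening peak between the two
  enlarging peaks, as observed in subtropical monitoring.
- **Tree heterogeneity.** Tree asymptotes are drawn from
  $N(A_{mean}, A_{sd}^2)$ truncated to positive values by resampling.
- **Dormancy gating.** Optionally, production is clamped to a growing
  window $[g_s, g_e]$ with tree-level jitter of both bounds. Without
  gating the pure mixture never quite stops producing, so enlargement
  would persist to the last sampling day in every tree; the gate
  reproduces the observed pattern of near-simultaneous onsets, earlier
  ends in older stands, and S-shaped totals that plateau before the
  fitted asymptote (as real seasons do).
- **Noise.** Poisson by default (integer counts, variance scaling with
  the mean); a rounded-Gaussian alternative gives controlled SD for
  calibration tests. Totals are re-derived as the sum of the four phases
  so the row invariant holds exactly. The true count noise structure of
  row-averaged micro-core readings is unknown; Poisson is an assumption,
  flagged as such.
- **Determinism.** Each tree's sub-seed is a stable hash of
  (seed, stand id, tree index), so adding a stand or tree never perturbs
  the draws of the others, and identical inputs are byte-identical.

`paper_scenarios()` provides five presets for an even-aged chronosequence
(planting years 2012–1969): asymptotes 94.7–358.5 cells with 20 %
between-tree CV, placement 1.38–1.68, and per-day rates 0.0064–0.0077
chosen inside the one-significant-figure rounding interval of published
fits so that $\beta/k$ matches each stand's reported rate-peak day;
growing windows open near day 72 everywhere and close progressively
earlier with age (day 300 down to 272). Five trees per stand sampled
every 9 days from day 51 to day 339 gives the canonical
$5 \times 5 \times 33 = 825$-observation design.

One structural point deserves emphasis: season-long Gompertz fits have
$k \approx 0.006$–$0.008$, which makes individual pulses so broad that a
two-pulse mixture with those per-pulse parameters does **not** resolve
into two distinct enlarging maxima — with $\Delta$ near 90 days the
expected trajectory is effectively unimodal, and the realised bimodality
of preset data comes from gating and noise rather than from pulse
separation. Cleanly resolved bimodality requires per-pulse sharpness well
above the season-long fit (grid-scan tests confirm two expected maxima
for splits 0.25–0.75 and offsets 60–125 days at $k = 0.07$).
`bimodal_scenario()` therefore builds validation stands with sharp pulses
($k = 0.05$ by default) placed so the enlarging peaks land near days 110
and 235, and peak-detection tests use it with a binding growing window
$[70, 262]$ and amplitude giving Poisson SNR $\approx 9$ at the first
peak. Under those conditions, onset/end and both peak days are recovered
within one sampling interval for $\ge 90\%$ of 100 simulated trees.

## What the tests show — and what they cannot

The simulation-backed checks demonstrate internal correctness: closed
forms agree with grid-search and finite-difference oracles; the estimator
recovers known parameters (exactly on noise-free real-valued data; with
about 90 % joint 2-SE coverage over replicates of the standard 5-tree
Poisson design at weekly sampling, days 30–340); detection rules recover
generator truth at field-like SNR; and LMG matches enumeration. They do
not validate the biological model against real micro-cores: real counts
have unknown noise structure, possible within-season autocorrelation,
missing collections, and observer variation that the generator does not
emulate. Passing tests show the pipeline does what its definitions say,
not that the Gompertz-plus-random-asymptote description is true of any
particular forest.

Problem sizes were chosen to keep the full suite quick: 20-replicate
recovery studies, 100-tree detection studies, and 825-row study
simulations all run in seconds on a single core.

## Known limitations

- Only the asymptote carries a random effect; random $\beta$ or $k$
  (timing/rate heterogeneity between trees) is out of scope, as are
  autocorrelated residuals and count-likelihood (GLMM) estimation.
- Alternative sigmoids (logistic, Weibull, Richards) are not offered.
- The kinetics of the per-tree rate regressor inherit the stand-level
  $\beta$ and $k$; trees differing mainly in timing would be
  misattributed to the asymptote.
- Phenology is assessed on the enlargement phase only; per-cohort
  durations of wall thickening are not derived.
- `run_study()` derives stand age as `reference_year − planting_year`
  (default 2019); for multi-year studies the reference must be set
  explicitly.
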