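#' Define a stand simulation scenario
#'
#' A scenario bundles everything needed to simulate one even-aged stand's
#' intra-annual wood-formation season: the population Gompertz kinetics of
#' cumulative cell production, between-tree asymptote heterogeneity (the
#' random effect), the within-season two-pulse structure that produces
#' bimodal cambial/enlarging dynamics, fixed residence times in the
#' enlarging and wall-thickening phases, the dormant cambial baseline, the
#' count noise model, and the micro-core sampling schedule.
#'
#' Cumulative production is a two-pulse Gompertz mixture
#' \deqn{P(t) = a [\, s\, g(t) + (1-s)\, g(t - \Delta)\,],\qquad
#'       g(t) = \exp(-\exp(\beta - k t)),}
#' with `s = pulse_split` and `\Delta = pulse2_offset`. `pulse_split = 1`
#' collapses to a single Gompertz. Phase counts follow by residence-time
#' differencing (see [generate_tree()]).
#'
#' @param stand_id Stand label (unique within a study).
#' @param planting_year Calendar year the stand was planted.
#' @param n_trees Number of monitored trees.
#' @param A_mean,A_sd Population mean and between-tree SD (cells) of the
#'   asymptote; the tree asymptote is drawn from
#'   Normal(`A_mean`, `A_sd`^2) truncated to positive values.
#' @param beta,k Per-pulse Gompertz placement and rate parameters.
#' @param pulse_split Fraction of production in the first within-season
#'   pulse, in \[0, 1\].
#' @param pulse2_offset Delay (days) of the second production pulse.
#' @param enlarge_days,thicken_days Residence times (days) in the enlarging
#'   and wall-thickening phases.
#' @param cambial_baseline Dormant cambial cell count (2--3 for realistic
#'   conifer presets).
#' @param cambial_gain Scaling (cells per cells/day) from instantaneous
#'   production rate to active cambial count above baseline.
#' @param noise_model `"poisson"` (integer counts, variance scaling with
#'   the mean) or `"rounded-gaussian"` (controlled SD, rounded and clamped
#'   at zero).
#' @param noise_sd Count SD for the rounded-Gaussian model (ignored for
#'   Poisson).
#' @param sampling_interval_days Days between micro-core collections
#'   (integer in 7--10).
#' @param season_start_doy,season_end_doy First and last sampling days of
#'   year (1-based, Jan 1 = 1).
#' @param grow_start_doy,grow_end_doy Population growing-window bounds:
#'   cell production is clamped to this window (dormancy outside it), so
#'   enlarging activity starts shortly after `grow_start_doy` and drains
#'   within one enlarging residence time after `grow_end_doy`. The
#'   defaults (`-Inf`, `Inf`) disable gating, in which case production is
#'   the pure two-pulse mixture.
#' @param onset_sd_days,end_sd_days Between-tree SD (days) of the
#'   tree-level growing-window bounds (only used when the corresponding
#'   bound is finite).
#'
#' @return An object of class `stand_scenario`.
#' @examples
#' sc <- stand_scenario("demo", 2012, A_mean = 120, A_sd = 15,
#'                      beta = 1.5, k = 0.007)
#' sc
#' @export
stand_scenario <- function(stand_id,
                           planting_year,
                           n_trees = 5,
                           A_mean = 120,
                           A_sd = 20,
                           beta = 1.5,
                           k = 0.007,
                           pulse_split = 1,
                           pulse2_offset = 90,
                           enlarge_days = 18,
                           thicken_days = 40,
                           cambial_baseline = 2.5,
                           cambial_gain = 10,
                           noise_model = c("poisson", "rounded-gaussian"),
                           noise_sd = 1,
                           sampling_interval_days = 9,
                           season_start_doy = 51,
                           season_end_doy = 340,
                           grow_start_doy = -Inf,
                           grow_end_doy = Inf,
                           onset_sd_days = 0,
                           end_sd_days = 0) {
  noise_model <- match.arg(noise_model)
  if (!is.finite(A_mean) || A_mean <= 0) stop("`A_mean` must be positive")
  if (!is.finite(A_sd) || A_sd < 0) stop("`A_sd` must be non-negative")
  if (!is.finite(k) || k <= 0) stop("`k` must be positive")
  if (pulse_split < 0 || pulse_split > 1) stop("`pulse_split` must lie in [0, 1]")
  if (enlarge_days <= 0 || thicken_days <= 0)
    stop("residence times must be positive")
  if (n_trees < 1) stop("`n_trees` must be at least 1")
  if (sampling_interval_days < 7 || sampling_interval_days > 10)
    stop("`sampling_interval_days` must be an integer in [7, 10]")
  if (season_end_doy <= season_start_doy) stop("empty sampling season")
  structure(list(
    stand_id = as.character(stand_id),
    planting_year = as.integer(planting_year),
    n_trees = as.integer(n_trees),
    A_mean = A_mean, A_sd = A_sd, beta = beta, k = k,
    pulse_split = pulse_split, pulse2_offset = pulse2_offset,
    enlarge_days = enlarge_days, thicken_days = thicken_days,
    cambial_baseline = cambial_baseline, cambial_gain = cambial_gain,
    noise_model = noise_model, noise_sd = noise_sd,
    sampling_interval_days = as.integer(sampling_interval_days),
    season_start_doy = as.integer(season_start_doy),
    season_end_doy = as.integer(season_end_doy),
    grow_start_doy = grow_start_doy,
    grow_end_doy = grow_end_doy,
    onset_sd_days = onset_sd_days,
    end_sd_days = end_sd_days
  ), class = "stand_scenario")
}

#' @export
print.stand_scenario <- function(x, ...) {
  cat(sprintf("Stand scenario '%s' (planted %d): %d trees\n",
              x$stand_id, x$planting_year, x$n_trees))
  cat(sprintf("  A ~ N(%.4g, %.4g^2), beta = %.4g, k = %.4g\n",
              x$A_mean, x$A_sd, x$beta, x$k))
  cat(sprintf("  pulses: split %.2f, offset %g d; residence: enlarge %g d, thicken %g d\n",
              x$pulse_split, x$pulse2_offset, x$enlarge_days, x$thicken_days))
  cat(sprintf("  noise: %s; sampling every %d d, DOY %d-%d\n",
              x$noise_model, x$sampling_interval_days,
              x$season_start_doy, x$season_end_doy))
  invisible(x)
}

unit_gompertz <- function(t, beta, k) exp(-exp(beta - k * t))
unit_gompertz_rate <- function(t, beta, k) {
  u <- exp(beta - k * t)
  k * u * exp(-u)
}

pulse_mixture <- function(doy, scenario) {
  s <- scenario$pulse_split
  s * unit_gompertz(doy, scenario$beta, scenario$k) +
    (1 - s) * unit_gompertz(doy - scenario$pulse2_offset,
                            scenario$beta, scenario$k)
}

pulse_mixture_rate <- function(doy, scenario) {
  s <- scenario$pulse_split
  s * unit_gompertz_rate(doy, scenario$beta, scenario$k) +
    (1 - s) * unit_gompertz_rate(doy - scenario$pulse2_offset,
                                 scenario$beta, scenario$k)
}

#' Cumulative cell production of a simulated tree
#'
#' Evaluates the two-pulse mixture \eqn{P(t)} defined by a scenario for a
#' given tree asymptote, non-decreasing in `doy`. Without growing-window
#' gating (the scenario default) this is the pure mixture, tending to
#' `tree_asymptote` as `doy` grows large; with a finite growing window,
#' production is clamped to the window (dormant outside), so the curve is
#' zero before the window opens and flat after it closes.
#'
#' @param doy Day(s) of year.
#' @param scenario A [stand_scenario()].
#' @param tree_asymptote Tree-level asymptote (cells).
#' @param grow_start,grow_end Growing-window bounds; default to the
#'   scenario's population bounds (tree-level draws override them inside
#'   [generate_tree()]).
#' @return Real-valued cumulative production at `doy`.
#' @export
cumulative_production <- function(doy, scenario, tree_asymptote,
                                  grow_start = scenario$grow_start_doy,
                                  grow_end = scenario$grow_end_doy) {
  tau <- pmin(pmax(doy, grow_start), grow_end)
  base <- if (is.finite(grow_start)) pulse_mixture(grow_start, scenario) else 0
  tree_asymptote * pmax(0, pulse_mixture(tau, scenario) - base)
}

#' Instantaneous cell-production rate of a simulated tree
#'
#' Analytic derivative of [cumulative_production()] with respect to day of
#' year (zero outside the growing window when gating is active); drives
#' the simulated active-cambium count.
#'
#' @inheritParams cumulative_production
#' @return Production rate in cells/day.
#' @export
production_rate <- function(doy, scenario, tree_asymptote,
                            grow_start = scenario$grow_start_doy,
                            grow_end = scenario$grow_end_doy) {
  inside <- doy >= grow_start & doy <= grow_end
  tree_asymptote * pulse_mixture_rate(doy, scenario) * as.numeric(inside)
}

sampling_grid <- function(scenario) {
  seq(scenario$season_start_doy, scenario$season_end_doy,
      by = scenario$sampling_interval_days)
}

# Stable 31-adic string hash folded into [0, 2^31 - 2]; keeps sub-seeds
# reproducible across platforms and independent between trees.
derive_seed <- function(seed, stand_id, tree_index) {
  key <- paste(seed, stand_id, tree_index, sep = "\x1f")
  h <- 17
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

draw_positive_normal <- function(mean, sd) {
  if (sd == 0) return(mean)
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
  stop("failed to draw a positive asymptote; check A_mean/A_sd")
}

apply_count_noise <- function(mu, scenario) {
  mu <- pmax(mu, 0)
  x <- switch(scenario$noise_model,
    "poisson" = stats::rpois(length(mu), mu),
    "rounded-gaussian" = round(mu + stats::rnorm(length(mu), 0, scenario$noise_sd))
  )
  pmax(as.integer(round(x)), 0L)
}

#' Simulate one tree's season of micro-core observations
#'
#' Draws the tree asymptote from the scenario's truncated-normal random
#' effect, builds expected phase counts at each sampling day by
#' residence-time differencing of cumulative production
#' (`enlarging(t) = P(t) - P(t - enlarge_days)`, wall-thickening the next
#' lag window, mature the fully lagged curve, cambial = baseline + gain x
#' dP/dt), applies the count noise model, and re-derives the total as the
#' sum of the four phases so the row invariant holds exactly.
#'
#' Identical `(scenario, tree_index, seed)` always yields identical output.
#'
#' @param scenario A [stand_scenario()].
#' @param tree_index Tree number within the stand (1-based).
#' @param seed Integer seed for this tree's random draws.
#' @return A tibble of per-sampling-day observations with columns
#'   `tree_id`, `stand_id`, `planting_year`, `doy`, `n_cambial`,
#'   `n_enlarging`, `n_thickening`, `n_mature`, `n_total`.
#' @export
generate_tree <- function(scenario, tree_index, seed) {
  if (!inherits(scenario, "stand_scenario")) stop("`scenario` must be a stand_scenario")
  if (tree_index < 1 || tree_index > scenario$n_trees)
    stop("`tree_index` out of range for this scenario")
  doy <- sampling_grid(scenario)
  old <- get_rng_state()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  a <- draw_positive_normal(scenario$A_mean, scenario$A_sd)
  gs <- scenario$grow_start_doy
  if (is.finite(gs) && scenario$onset_sd_days > 0)
    gs <- gs + stats::rnorm(1, 0, scenario$onset_sd_days)
  ge <- scenario$grow_end_doy
  if (is.finite(ge) && scenario$end_sd_days > 0)
    ge <- ge + stats::rnorm(1, 0, scenario$end_sd_days)
  P <- function(t) cumulative_production(t, scenario, a, gs, ge)
  le <- scenario$enlarge_days
  lt <- scenario$thicken_days

  e_enl <- P(doy) - P(doy - le)
  e_thk <- P(doy - le) - P(doy - le - lt)
  e_mat <- P(doy - le - lt)
  e_cam <- scenario$cambial_baseline +
    scenario$cambial_gain * production_rate(doy, scenario, a, gs, ge)

  tibble::tibble(
    tree_id = sprintf("%s_T%d", scenario$stand_id, tree_index),
    stand_id = scenario$stand_id,
    planting_year = scenario$planting_year,
    doy = as.integer(doy),
    n_cambial = apply_count_noise(e_cam, scenario),
    n_enlarging = apply_count_noise(e_enl, scenario),
    n_thickening = apply_count_noise(e_thk, scenario),
    n_mature = apply_count_noise(e_mat, scenario)
  ) |>
    dplyr::mutate(n_total = .data$n_cambial + .data$n_enlarging +
                    .data$n_thickening + .data$n_mature)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a whole multi-stand monitoring study
#'
#' Concatenates [generate_tree()] output over every scenario and tree. Each
#' tree receives a deterministic sub-seed hashed from
#' `(seed, stand_id, tree_index)`, so adding a stand or tree never perturbs
#' the draws of the others.
#'
#' @param scenarios A list of [stand_scenario()] objects with distinct
#'   `stand_id`s (a single scenario may be passed bare).
#' @param seed Top-level integer seed.
#' @return A long-format tibble of observations (see [generate_tree()]).
#' @examples
#' study <- generate_study(paper_scenarios(), seed = 1)
#' nrow(study)  # 5 stands x 5 trees x 33 sampling dates = 825
#' @export
generate_study <- function(scenarios, seed) {
  if (inherits(scenarios, "stand_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0) stop("`scenarios` must be non-empty")
  ids <- vapply(scenarios, function(s) s$stand_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate stand_id in `scenarios`: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  purrr::map_dfr(scenarios, function(sc) {
    purrr::map_dfr(seq_len(sc$n_trees), function(i) {
      generate_tree(sc, i, derive_seed(seed, sc$stand_id, i))
    })
  })
}

#' Scenario presets for a five-age-class Chinese fir study
#'
#' Five stand scenarios (planting years 2012, 2006, 2000, 1993 and 1969;
#' young through over-mature) whose population kinetics follow published
#' Gompertz fits for such stands: asymptotes 94.7--358.5 cells, placement
#' 1.38--1.68, per-day rates 0.0064--0.008 chosen so the inflection date
#' beta/k matches the reported rate-peak day of each stand. Five trees per
#' stand sampled every 9 days from DOY 51 to DOY 339 (33 collections),
#' Poisson count noise, dormant cambial baseline 2.5 cells. Growing
#' windows open near DOY 72 in every stand (onsets of enlargement are
#' age-invariant) and close progressively earlier with stand age (DOY 300
#' down to 272), reproducing the observed pattern of similar onsets,
#' age-ordered ends and durations, with tree-level window jitter (SD 4 and
#' 10 days).
#'
#' @param n_trees Trees per stand.
#' @return A named list of five [stand_scenario()] objects
#'   (`paper2012` ... `paper1969`).
#' @export
paper_scenarios <- function(n_trees = 5) {
  presets <- list(
    paper2012 = list(year = 2012, A = 358.5, beta = 1.68, k = 0.0064, ge = 300),
    paper2006 = list(year = 2006, A = 116.4, beta = 1.46, k = 0.0073, ge = 298),
    paper2000 = list(year = 2000, A = 243.4, beta = 1.67, k = 0.0073, ge = 288),
    paper1993 = list(year = 1993, A = 123.4, beta = 1.49, k = 0.0075, ge = 280),
    paper1969 = list(year = 1969, A = 94.7,  beta = 1.38, k = 0.0077, ge = 272)
  )
  lapply(presets, function(s) {
    stand_scenario(
      stand_id = as.character(s$year), planting_year = s$year,
      n_trees = n_trees,
      A_mean = s$A, A_sd = 0.2 * s$A, beta = s$beta, k = s$k,
      pulse_split = 0.55, pulse2_offset = 90,
      grow_start_doy = 72, grow_end_doy = s$ge,
      onset_sd_days = 4, end_sd_days = 10
    )
  })
}

#' Scenario with clearly resolved bimodal enlarging dynamics
#'
#' A stand whose two production pulses are sharp enough (per-pulse k well
#' above the season-long fits) that the expected enlarging-cell trajectory
#' shows two separated within-season maxima, placed by default near DOY 110
#' and DOY 235 as observed in subtropical conifer monitoring. Used for
#' validating peak detection against known truth.
#'
#' @param first_peak_doy,second_peak_doy Target DOYs of the two enlarging
#'   maxima.
#' @param pulse_k Per-pulse rate parameter (sharpness).
#' @param pulse_split Share of production in the first pulse (> 0.5 makes
#'   the second maximum the smaller one, the typical field pattern).
#' @param A_mean,A_sd Population asymptote mean and between-tree SD.
#' @param ... Further arguments passed to [stand_scenario()].
#' @return A [stand_scenario()].
#' @export
bimodal_scenario <- function(first_peak_doy = 110, second_peak_doy = 235,
                             pulse_k = 0.05, pulse_split = 0.6,
                             A_mean = 150, A_sd = 20, ...) {
  # An enlarging peak sits near the pulse inflection plus half the
  # enlarging residence time; place the pulse accordingly.
  enlarge_days <- 18
  t1 <- first_peak_doy - enlarge_days / 2
  stand_scenario(
    stand_id = "bimodal", planting_year = 2012,
    A_mean = A_mean, A_sd = A_sd,
    beta = pulse_k * t1, k = pulse_k,
    pulse_split = pulse_split,
    pulse2_offset = second_peak_doy - first_peak_doy,
    enlarge_days = enlarge_days,
    ...
  )
}

#' Clean single-pulse scenario for parameter-recovery studies
#'
#' A single-pulse scenario whose expected total count is exactly the
#' Gompertz curve (cambial machinery switched off), so fitted fixed effects
#' can be compared against known truth without phase-structure bias.
#'
#' @param A_mean,A_sd,beta,k Population parameters (defaults give a
#'   mid-sized stand with moderate tree heterogeneity).
#' @param n_trees Trees per stand.
#' @param ... Further arguments passed to [stand_scenario()].
#' @return A [stand_scenario()].
#' @export
recovery_scenario <- function(A_mean = 120, A_sd = 15, beta = 1.5, k = 0.007,
                              n_trees = 5, ...) {
  stand_scenario(
    stand_id = "recovery", planting_year = 2000, n_trees = n_trees,
    A_mean = A_mean, A_sd = A_sd, beta = beta, k = k,
    pulse_split = 1,
    cambial_baseline = 0, cambial_gain = 0,
    sampling_interval_days = 7,
    season_start_doy = 30, season_end_doy = 340,
    ...
  )
}

#' Read and write stand scenarios as plain-text configuration
#'
#' Scenarios serialise to a YAML file with one named block per stand,
#' mirroring the [stand_scenario()] arguments. A preset file with the five
#' age-class scenarios ships in `system.file("extdata",
#' "stand_presets.yaml", package = "xylodyn")`.
#'
#' @param path File path.
#' @return `read_scenarios()` returns a named list of scenarios;
#'   `write_scenarios()` returns `path` invisibly.
#' @export
read_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(block) do.call(stand_scenario, block))
}

#' @rdname read_scenarios
#' @param scenarios Named list of [stand_scenario()] objects.
#' @export
write_scenarios <- function(scenarios, path) {
  blocks <- lapply(scenarios, function(s) unclass(s))
  yaml::write_yaml(blocks, path)
  invisible(path)
}
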