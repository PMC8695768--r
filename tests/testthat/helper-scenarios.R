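# Shared builders for simulation-backed tests.

# Gated bimodal stand with strong counts: enlarging peaks near DOY 110 and
# 235, production window [70, 262] so enlargement drains out by DOY 280.
sharp_bimodal_scenario <- function(n_trees = 5, ...) {
  sc <- bimodal_scenario(A_mean = 400, A_sd = 40,
                         grow_start_doy = 70, grow_end_doy = 262,
                         onset_sd_days = 0, end_sd_days = 0, ...)
  sc$n_trees <- as.integer(n_trees)
  sc
}

# Noise-free variant of any scenario (rounded-gaussian with sd 0: counts
# are the rounded expected values).
noiseless <- function(sc) {
  sc$noise_model <- "rounded-gaussian"
  sc$noise_sd <- 0
  sc
}

quiet_fit <- function(...) suppressWarnings(fit_stand(...))

# Real-valued (unrounded) noiseless observations of a single-pulse
# scenario: the exact mixed-model mean function, for optimizer-tolerance
# recovery checks.
exact_total_observations <- function(sc, asymptotes) {
  doy <- seq(sc$season_start_doy, sc$season_end_doy,
             by = sc$sampling_interval_days)
  purrr::map_dfr(seq_along(asymptotes), function(i) {
    tibble::tibble(
      tree_id = sprintf("T%d", i), stand_id = sc$stand_id,
      planting_year = sc$planting_year, doy = doy,
      n_total = cumulative_production(doy, sc, asymptotes[i])
    )
  })
}
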