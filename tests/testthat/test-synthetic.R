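test_that("single-pulse production is exactly the Gompertz curve", {
  sc <- stand_scenario("s", 2000, A_mean = 100, A_sd = 0, beta = 1.5,
                       k = 0.02, pulse_split = 1, pulse2_offset = 999)
  t <- seq(1, 365, by = 1)
  expect_equal(cumulative_production(t, sc, 100),
               gompertz_value(t, gompertz_params(100, 1.5, 0.02)))
})

test_that("production is non-decreasing and tends to the tree asymptote", {
  sc <- stand_scenario("s", 2000, A_mean = 100, A_sd = 0, beta = 1.5,
                       k = 0.02, pulse_split = 0.5, pulse2_offset = 80)
  t <- seq(1, 365, by = 0.5)
  P <- cumulative_production(t, sc, 100)
  expect_true(all(diff(P) >= 0))
  expect_equal(cumulative_production(5000, sc, 100), 100, tolerance = 1e-6)
})

test_that("well-separated sharp pulses give exactly two expected enlarging maxima", {
  # grid-scan oracle over split and offset; per-pulse k sharp enough that
  # pulses separated by >= 60 days resolve
  grid <- seq(20, 360, by = 1)
  count_local_maxima <- function(y) {
    i <- 2:(length(y) - 1)
    sum(y[i] > y[i - 1] & y[i] >= y[i + 1])
  }
  for (split in c(0.25, 0.5, 0.75)) {
    for (offset in c(60, 90, 125)) {
      sc <- stand_scenario("s", 2000, A_mean = 100, A_sd = 0, beta = 7,
                           k = 0.07, pulse_split = split,
                           pulse2_offset = offset)
      e_enl <- cumulative_production(grid, sc, 100) -
        cumulative_production(grid - sc$enlarge_days, sc, 100)
      expect_equal(count_local_maxima(e_enl), 2)
    }
  }
})

test_that("tree generation is deterministic in (scenario, tree, seed)", {
  sc <- paper_scenarios()[["paper2012"]]
  a <- generate_tree(sc, 2, seed = 123)
  b <- generate_tree(sc, 2, seed = 123)
  expect_identical(a, b)
  d <- generate_tree(sc, 2, seed = 124)
  expect_false(identical(a, d))
  expect_identical(a$doy, d$doy)  # same grid, different noise
})

test_that("noiseless single-pulse mature series is the rounded lagged curve", {
  sc <- noiseless(stand_scenario("s", 2000, A_mean = 150, A_sd = 0,
                                 beta = 1.5, k = 0.02, pulse_split = 1))
  obs <- generate_tree(sc, 1, seed = 5)
  lag <- sc$enlarge_days + sc$thicken_days
  expected <- round(gompertz_value(obs$doy - lag, gompertz_params(150, 1.5, 0.02)))
  expect_equal(obs$n_mature, as.integer(expected))
  expect_true(all(diff(obs$n_mature) >= 0))
})

test_that("every generated row satisfies the observation invariants", {
  # ~13k rows across heterogeneous scenarios
  scs <- paper_scenarios(n_trees = 80)
  obs <- generate_study(scs[c("paper2012", "paper2000", "paper1969")], seed = 31)
  obs2 <- generate_study(list(sharp_bimodal_scenario(n_trees = 80)), seed = 32)
  all_rows <- dplyr::bind_rows(obs, obs2)
  expect_gt(nrow(all_rows), 10000)
  counts <- all_rows[, c("n_cambial", "n_enlarging", "n_thickening",
                         "n_mature", "n_total")]
  expect_true(all(as.matrix(counts) >= 0))
  expect_true(all(as.matrix(counts) == round(as.matrix(counts))))
  expect_identical(all_rows$n_total,
                   all_rows$n_cambial + all_rows$n_enlarging +
                     all_rows$n_thickening + all_rows$n_mature)
})

test_that("mature counts are near-monotone under bounded noise", {
  sc <- paper_scenarios()[["paper2000"]]
  sc$noise_model <- "rounded-gaussian"
  sc$noise_sd <- 2
  for (i in 1:5) {
    obs <- generate_tree(sc, 1, seed = 400 + i)
    iso <- stats::isoreg(obs$doy, obs$n_mature)
    expect_true(all(abs(iso$yf - obs$n_mature) <= 3 * sc$noise_sd))
  }
})

test_that("the five-stand study has the expected size and composition", {
  study <- generate_study(paper_scenarios(), seed = 1)
  expect_identical(nrow(study), 825L)  # 5 stands x 5 trees x 33 dates
  expect_identical(length(unique(study$stand_id)), 5L)
  expect_identical(length(unique(study$tree_id)), 25L)
  expect_identical(length(unique(study$doy)), 33L)
})

test_that("study generation composes from tree generation with stable sub-seeds", {
  sc <- paper_scenarios()[["paper1993"]]
  sc$n_trees <- 1L
  study <- generate_study(list(sc), seed = 9)
  # base case: one stand, one tree
  direct <- generate_tree(sc, 1, xylodyn:::derive_seed(9, sc$stand_id, 1))
  expect_identical(study, direct)
  # different top seeds: same DOY grid, different realizations
  s1 <- generate_study(paper_scenarios(), seed = 1)
  s2 <- generate_study(paper_scenarios(), seed = 2)
  expect_identical(s1$doy, s2$doy)
  expect_false(identical(s1$n_total, s2$n_total))
})

test_that("scenario validation rejects bad parameters", {
  expect_error(stand_scenario("s", 2000, A_mean = -5), "positive")
  expect_error(stand_scenario("s", 2000, pulse_split = 1.2), "pulse_split")
  expect_error(stand_scenario("s", 2000, enlarge_days = 0), "residence")
  expect_error(stand_scenario("s", 2000, sampling_interval_days = 12), "7, 10")
  scs <- paper_scenarios()
  expect_error(generate_study(list(scs[[1]], scs[[1]]), seed = 1), "duplicate")
})

test_that("a single Gompertz fits the young-stand preset totals well", {
  sc <- paper_scenarios()[["paper2012"]]
  obs <- generate_study(list(sc), seed = 21)
  fit <- quiet_fit(obs)
  expect_gte(fit$r_squared, 0.85)
})

test_that("per-tree fitted asymptotes recover the population mean", {
  # 50 independent trees, individual curve fits; Monte-Carlo mean of the
  # asymptotes within 2 standard errors of A_mean. The season must cover
  # the plateau (k = 0.02 here) or the extrapolated asymptote is biased.
  sc <- recovery_scenario(n_trees = 50, beta = 1.5, k = 0.02)
  obs <- generate_study(list(sc), seed = 77)
  a_hat <- vapply(split(obs, obs$tree_id), function(d) {
    fit <- minpack.lm::nlsLM(n_total ~ A * exp(-exp(beta - k * doy)),
                             data = d,
                             start = list(A = 1.05 * max(d$n_total),
                                          beta = 1.5, k = 0.02))
    coef(fit)[["A"]]
  }, numeric(1))
  se <- sd(a_hat) / sqrt(length(a_hat))
  expect_lt(abs(mean(a_hat) - 120), 2 * se + 1e-9)
})

test_that("scenario presets roundtrip through the plain-text config", {
  path <- file.path(tempdir(), "scenarios.yaml")
  write_scenarios(paper_scenarios(), path)
  back <- read_scenarios(path)
  # YAML carries ~15 significant digits, so equality up to serialization
  expect_equal(back, paper_scenarios(), tolerance = 1e-12)
  shipped <- system.file("extdata", "stand_presets.yaml", package = "xylodyn")
  expect_equal(read_scenarios(shipped), paper_scenarios(), tolerance = 1e-12)
})
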