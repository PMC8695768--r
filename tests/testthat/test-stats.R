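test_that("age trend ANOVA matches a hand-computed decomposition", {
  # 6-point fixture solved by explicit normal equations
  d <- data.frame(age = c(8, 8, 20, 20, 51, 51),
                  y = c(100, 104, 80, 86, 60, 58))
  out <- age_trend_anova(d, y, age)
  b <- cov(d$age, d$y) / var(d$age)
  fitted <- mean(d$y) + b * (d$age - mean(d$age))
  ss_reg <- sum((fitted - mean(d$y))^2)
  ss_res <- sum((d$y - fitted)^2)
  expect_equal(out$sumsq, c(ss_reg, ss_res))
  expect_equal(out$meansq, c(ss_reg / 1, ss_res / 4))
  expect_equal(out$statistic[1], (ss_reg / 1) / (ss_res / 4))
  expect_equal(out$p.value[1], pf(out$statistic[1], 1, 4, lower.tail = FALSE))
  expect_identical(out$df, c(1L, 4L))
})

test_that("the 1-df F statistic is the squared slope t statistic", {
  set.seed(91)
  d <- data.frame(age = rep(c(8, 14, 20, 27, 51), each = 5))
  d$y <- 100 - 0.8 * d$age + rnorm(25, sd = 10)
  out <- age_trend_anova(d, y, age)
  tstat <- summary(lm(y ~ age, d))$coefficients["age", "t value"]
  expect_equal(out$statistic[1], tstat^2, tolerance = 1e-10)
})

test_that("a perfect linear age trend leaves no residual variance", {
  d <- data.frame(age = c(8, 14, 20, 27, 51), y = 2 + 3 * c(8, 14, 20, 27, 51))
  out <- suppressWarnings(age_trend_anova(d, y, age))  # perfect-fit F warning
  expect_lt(out$sumsq[2], 1e-18)
  expect_lt(out$p.value[1], 1e-12)
})

test_that("factor mode runs a classical one-way ANOVA over age classes", {
  set.seed(92)
  d <- data.frame(age = rep(c(8, 14, 20, 27, 51), each = 5))
  d$y <- rnorm(25) + rep(c(0, 1, 0, 2, 0), each = 5)
  out <- age_trend_anova(d, y, age, mode = "factor")
  expect_identical(out$df[1], 4L)
  expect_equal(out$sumsq, as.numeric(anova(lm(y ~ factor(age), d))$`Sum Sq`))
})

test_that("the age-independent null keeps its nominal type-I error", {
  # permutation study: F computed from the squared correlation
  set.seed(93)
  age <- rep(c(8, 14, 20, 27, 51), each = 5)
  y <- rnorm(25)
  n <- length(y)
  fstat <- vapply(1:1000, function(i) {
    r2 <- cor(age, sample(y))^2
    (n - 2) * r2 / (1 - r2)
  }, numeric(1))
  rejection <- mean(fstat > qf(0.95, 1, n - 2))
  expect_gte(rejection, 0.03)
  expect_lte(rejection, 0.07)
})

test_that("age ANOVA rejects degenerate inputs", {
  expect_error(age_trend_anova(data.frame(a = 1, y = 1), y, a), "3 trees")
  expect_error(age_trend_anova(data.frame(a = c(1, 1, 1), y = c(1, 2, 3)), y, a),
               "distinct ages")
  expect_error(age_trend_anova(data.frame(a = c(1, 2, 3), y = c(5, 5, 5)), y, a),
               "constant")
})

test_that("the rate-duration model recovers exact coefficients without noise", {
  set.seed(94)
  d <- data.frame(rate = runif(12, 0.1, 0.9), dur = runif(12, 200, 250))
  d$cells <- -50 + 400 * d$rate + 0.2 * d$dur
  fit <- fit_rate_duration(d, cells, rate, dur)
  td <- suppressWarnings(tidy(fit))  # perfect-fit warning from summary.lm
  expect_equal(td$estimate, c(-50, 400, 0.2), tolerance = 1e-9)
  expect_equal(suppressWarnings(glance(fit))$r.squared, 1, tolerance = 1e-12)
})

test_that("the rate-duration model matches a normal-equations solve", {
  set.seed(95)
  d <- data.frame(rate = runif(10, 0.2, 0.8), dur = runif(10, 210, 240))
  d$cells <- -56 + 397 * d$rate + 0.19 * d$dur + rnorm(10, sd = 5)
  fit <- fit_rate_duration(d, cells, rate, dur)
  X <- cbind(1, d$rate, d$dur)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d$cells)
  expect_equal(tidy(fit)$estimate, as.numeric(beta_hat), tolerance = 1e-8)
  # normal equations: residuals orthogonal to every design column
  resid <- d$cells - X %*% beta_hat
  expect_lt(max(abs(t(X) %*% resid)), 1e-8)
})

test_that("a constant duration column raises a rank-deficiency error", {
  d <- data.frame(rate = runif(8), dur = 220, cells = rnorm(8))
  expect_error(fit_rate_duration(d, cells, rate, dur), "dur")
  expect_error(fit_rate_duration(d[1:3, ], cells, rate, dur), "4 trees")
})

test_that("two-predictor LMG equals its closed form and sums to full R^2", {
  set.seed(96)
  for (i in 1:10) {
    n <- 40
    x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
    y <- 2 * x1 + x2 + rnorm(n)
    d <- data.frame(y, x1, x2)
    out <- lmg_importance(d, y, x1, x2)
    r2 <- function(form) summary(lm(form, d))$r.squared
    full <- r2(y ~ x1 + x2)
    share1 <- 0.5 * (r2(y ~ x1) + (full - r2(y ~ x2)))
    share2 <- 0.5 * (r2(y ~ x2) + (full - r2(y ~ x1)))
    expect_equal(out$contributions$lmg, c(share1, share2), tolerance = 1e-10)
    expect_equal(sum(out$contributions$lmg), full, tolerance = 1e-10)
    expect_equal(sum(out$contributions$lmg_normalized), 1, tolerance = 1e-10)
  }
})

test_that("LMG matches brute-force enumeration of orderings for 3 predictors", {
  set.seed(97)
  n <- 50
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 1.5 * d$x1 + d$x2 - 0.5 * d$x3 + 0.4 * d$x1 * 0 + rnorm(n)
  out <- lmg_importance(d, y, x1, x2, x3)
  X <- as.matrix(d[, c("x1", "x2", "x3")])
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    f <- lm.fit(cbind(1, X[, cols, drop = FALSE]), d$y)
    1 - sum(f$residuals^2) / sum((d$y - mean(d$y))^2)
  }
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  brute <- numeric(3)
  for (perm in perms) {
    for (pos in seq_along(perm)) {
      j <- perm[pos]
      before <- perm[seq_len(pos - 1)]
      brute[j] <- brute[j] + (r2(c(before, j)) - r2(before)) / length(perms)
    }
  }
  expect_equal(out$contributions$lmg, brute, tolerance = 1e-10)
  expect_equal(sum(out$contributions$lmg), r2(1:3), tolerance = 1e-10)
})

test_that("LMG is invariant to predictor input order", {
  set.seed(98)
  d <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  d$y <- d$x1 + 0.3 * d$x2 + rnorm(30, sd = 0.5)
  a <- lmg_importance(d, y, x1, x2)$contributions
  b <- lmg_importance(d, y, x2, x1)$contributions
  expect_equal(a$lmg[a$predictor == "x1"], b$lmg[b$predictor == "x1"],
               tolerance = 1e-12)
})

test_that("orthogonal predictors split by marginal R^2; duplicates split 50/50", {
  # exactly orthogonal, centered design
  x1 <- rep(c(-1, 1), each = 8)
  x2 <- rep(c(-1, 1), times = 8)
  set.seed(99)
  y <- 2 * x1 + x2 + rnorm(16, sd = 0.3)
  d <- data.frame(y, x1, x2)
  out <- lmg_importance(d, y, x1, x2)
  r2 <- function(form) summary(lm(form, d))$r.squared
  marg <- c(r2(y ~ x1), r2(y ~ x2))
  expect_equal(out$contributions$lmg_normalized, marg / sum(marg),
               tolerance = 1e-10)
  # duplicated predictor: shared variance splits symmetrically
  d2 <- data.frame(y, x1, x1b = x1)
  dup <- lmg_importance(d2, y, x1, x1b)
  expect_equal(dup$contributions$lmg_normalized, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(dup$contributions$lmg), r2(y ~ x1), tolerance = 1e-12)
})

test_that("rate dominates duration under rate-heavy heterogeneity", {
  # wide spread of rates (0.27-0.83 cells/day), narrow spread of durations
  # (211-243 days): the final cell number is driven by rate
  set.seed(100)
  n <- 25
  rate <- runif(n, 0.27, 0.83)
  duration <- runif(n, 211, 243)
  cells <- -56 + 397 * rate + 0.19 * duration + rnorm(n, sd = 10)
  d <- data.frame(cells, rate, duration)
  out <- lmg_importance(fit_rate_duration(d, cells, rate, duration))
  shares <- out$contributions
  expect_gt(shares$lmg[shares$predictor == "rate"],
            shares$lmg[shares$predictor == "duration"])
})

test_that("LMG rejects degenerate inputs", {
  d <- data.frame(y = rnorm(10), x1 = rnorm(10), x2 = 1)
  expect_error(lmg_importance(d, y, x1, x2), "constant predictor")
  expect_error(lmg_importance(d[1:2, ], y, x1), "observations")
})
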