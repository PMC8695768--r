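#' Age-trend test for a per-tree growth characteristic
#'
#' Tests whether a per-tree quantity (final cell number, onset, end,
#' duration, rate-peak day, maximal or average rate) changes with stand
#' age. The default enters age as a single numeric covariate, giving the
#' 1-df regression ANOVA line (slope F-test, equivalent to the squared
#' slope t-statistic); `mode = "factor"` instead runs a classical one-way
#' ANOVA over age classes.
#'
#' @param data Data frame with one row per tree.
#' @param value Column (tidy-eval) holding the tested per-tree quantity.
#' @param age Column (tidy-eval) holding tree/stand age in years.
#' @param mode `"numeric"` (age as covariate, 1 df, default) or
#'   `"factor"` (age-class one-way ANOVA).
#' @return A tibble with the ANOVA rows (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`): the age term first, then residuals.
#' @examples
#' d <- data.frame(age = rep(c(8, 14, 20, 27, 51), each = 5),
#'                 y = rnorm(25, 100 - rep(c(8, 14, 20, 27, 51), each = 5)))
#' age_trend_anova(d, y, age)
#' @export
age_trend_anova <- function(data, value, age, mode = c("numeric", "factor")) {
  mode <- match.arg(mode)
  y <- dplyr::pull(data, {{ value }})
  a <- dplyr::pull(data, {{ age }})
  if (length(y) < 3) stop("need at least 3 trees")
  if (length(unique(a)) < 2) stop("need at least 2 distinct ages")
  if (stats::var(y) == 0) stop("response is constant; F undefined")
  x <- if (mode == "numeric") a else factor(a)
  fit <- stats::lm(y ~ x)
  tab <- stats::anova(fit)
  tibble::tibble(
    term = c("age", "residuals"),
    df = tab$Df,
    sumsq = tab$`Sum Sq`,
    meansq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p.value = tab$`Pr(>F)`
  )
}

#' Linear model of final cell number against rate and duration
#'
#' Ordinary least squares for \eqn{Y = \alpha_0 + \alpha_1 x_1 + \alpha_2
#' x_2}, where \eqn{Y} is each tree's final cell count of the season,
#' \eqn{x_1} its rate of xylem cell formation (cells/day) and \eqn{x_2}
#' the duration of its growing period (days).
#'
#' @param data Data frame with one row per tree.
#' @param total,rate,duration Columns (tidy-eval) holding \eqn{Y},
#'   \eqn{x_1} and \eqn{x_2}.
#' @return An object of class `rate_duration_fit` wrapping the `lm` fit;
#'   use [tidy.rate_duration_fit()] / [glance.rate_duration_fit()] or pass
#'   it to [lmg_importance()].
#' @export
fit_rate_duration <- function(data, total, rate, duration) {
  d <- data.frame(
    Y = dplyr::pull(data, {{ total }}),
    rate = dplyr::pull(data, {{ rate }}),
    duration = dplyr::pull(data, {{ duration }})
  )
  if (nrow(d) < 4) stop("need at least 4 trees")
  X <- stats::model.matrix(~ rate + duration, d)
  if (qr(X)$rank < ncol(X)) {
    degen <- names(which(apply(X[, -1, drop = FALSE], 2, stats::var) == 0))
    stop("rank-deficient design; collinear or constant column(s): ",
         if (length(degen)) paste(degen, collapse = ", ") else "rate/duration")
  }
  fit <- stats::lm(Y ~ rate + duration, data = d)
  structure(list(lm = fit, data = tibble::as_tibble(d)),
            class = "rate_duration_fit")
}

#' @export
print.rate_duration_fit <- function(x, ...) {
  co <- stats::coef(x$lm)
  cat("Final cell number vs rate and duration (OLS)\n")
  cat(sprintf("  Y = %.4g + %.4g * rate + %.4g * duration,  R^2 = %.3f\n",
              co[1], co[2], co[3], summary(x$lm)$r.squared))
  invisible(x)
}

#' Tidy the rate--duration model
#'
#' @param x A [fit_rate_duration()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` for intercept, rate and duration.
#' @export
tidy.rate_duration_fit <- function(x, ...) {
  co <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "rate", "duration"),
    estimate = unname(co[, 1]), std.error = unname(co[, 2]),
    statistic = unname(co[, 3]), p.value = unname(co[, 4])
  )
}

#' @rdname tidy.rate_duration_fit
#' @return `glance()`: one-row tibble with `r.squared`,
#'   `adj.r.squared`, `sigma`, `statistic`, `p.value`, `df.residual`,
#'   `n_obs`.
#' @export
glance.rate_duration_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    statistic = unname(f[1]),
    p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
    df.residual = x$lm$df.residual,
    n_obs = nrow(x$data)
  )
}

r2_of_subset <- function(y, X, subset) {
  if (length(subset) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, X[, subset, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' LMG relative-importance decomposition of a linear model's R-squared
#'
#' Allocates the full-model coefficient of determination among predictors
#' by the LMG rule: each predictor's share is the average, over all
#' orderings of the predictors, of the increase in R² when it enters the
#' model. Computed over predictor subsets with factorial weights
#' \eqn{|S|!\,(p-|S|-1)!/p!}, which is exact and identical to averaging
#' over all \eqn{p!} orderings. The unnormalised shares always sum to the
#' full-model R²; normalised shares divide by it.
#'
#' @param x Either a [fit_rate_duration()] result (its two predictors are
#'   decomposed), or a data frame.
#' @param response,... For the data-frame method: the response column and
#'   the predictor columns (tidy-eval).
#' @return An object of class `lmg_importance` with `contributions` (a
#'   tibble with `predictor`, `lmg`, `lmg_normalized`) and
#'   `total_r_squared`.
#' @examples
#' d <- data.frame(y = rnorm(30), a = rnorm(30), b = rnorm(30))
#' d$y <- d$a + 0.3 * d$b + rnorm(30, sd = 0.2)
#' lmg_importance(d, y, a, b)
#' @export
lmg_importance <- function(x, ...) UseMethod("lmg_importance")

#' @rdname lmg_importance
#' @export
lmg_importance.rate_duration_fit <- function(x, ...) {
  lmg_importance(x$data, "Y", "rate", "duration")
}

#' @rdname lmg_importance
#' @export
lmg_importance.data.frame <- function(x, response, ...) {
  y <- dplyr::pull(x, {{ response }})
  preds <- dplyr::select(x, ...)
  p <- ncol(preds)
  if (p < 1) stop("supply at least one predictor column")
  if (nrow(preds) < p + 2) stop("need at least p + 2 observations")
  X <- as.matrix(preds)
  if (any(apply(X, 2, stats::var) == 0))
    stop("constant predictor column; no variance to allocate")
  if (stats::var(y) == 0) stop("response is constant")
  # collinear (even duplicated) predictors are allowed: every subset R^2 is
  # the well-defined projection onto the subset's column space, and LMG
  # splits the shared variance symmetrically

  full <- r2_of_subset(y, X, seq_len(p))
  shares <- vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    total <- 0
    for (m in 0:length(others)) {
      subsets <- if (m == 0) list(integer(0)) else
        utils::combn(others, m, simplify = FALSE)
      w <- factorial(m) * factorial(p - m - 1) / factorial(p)
      for (S in subsets) {
        total <- total + w * (r2_of_subset(y, X, c(S, j)) - r2_of_subset(y, X, S))
      }
    }
    total
  }, numeric(1))

  structure(list(
    contributions = tibble::tibble(
      predictor = colnames(preds),
      lmg = shares,
      lmg_normalized = if (full > 0) shares / full else rep(NA_real_, p)
    ),
    total_r_squared = full,
    n_obs = nrow(preds)
  ), class = "lmg_importance")
}

#' @export
print.lmg_importance <- function(x, ...) {
  cat(sprintf("LMG relative importance (full-model R^2 = %.4f)\n",
              x$total_r_squared))
  with(x$contributions, for (i in seq_along(predictor)) {
    cat(sprintf("  %-12s %6.1f%% of explained variance (R^2 share %.4f)\n",
                predictor[i], 100 * lmg_normalized[i], lmg[i]))
  })
  invisible(x)
}

#' @export
tidy.lmg_importance <- function(x, ...) x$contributions

#' @export
glance.lmg_importance <- function(x, ...) {
  tibble::tibble(total_r_squared = x$total_r_squared, n_obs = x$n_obs)
}
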