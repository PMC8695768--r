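response_column <- function(response = c("total", "mature", "enlarging",
                                         "thickening", "cambial")) {
  response <- match.arg(response)
  paste0("n_", switch(response, total = "total", mature = "mature",
                      enlarging = "enlarging", thickening = "thickening",
                      cambial = "cambial"))
}

# Deterministic starting values: A0 slightly above the observed maximum,
# then OLS on the log-log linearisation log(-log(y/A0)) = beta - k t using
# interior points only.
gompertz_start <- function(doy, y) {
  A0 <- 1.05 * max(y)
  frac <- y / A0
  keep <- frac > 0.05 & frac < 0.95
  if (sum(keep) >= 3) {
    z <- log(-log(frac[keep]))
    fit <- stats::lm(z ~ doy[keep])
    beta0 <- unname(stats::coef(fit)[1])
    k0 <- -unname(stats::coef(fit)[2])
  } else {
    beta0 <- NA_real_
    k0 <- NA_real_
  }
  if (!is.finite(k0) || k0 <= 0) {
    k0 <- 4.07 / diff(range(doy))    # 5-95% window spanning the season
    beta0 <- k0 * stats::median(doy)
  }
  c(A = A0, beta = beta0, k = k0)
}

#' Fit the Gompertz stand model with a tree-level random asymptote
#'
#' Fits \eqn{Y_{ij} = (A + a_i)\exp(-\exp(\beta - k\, t_{ij})) +
#' \epsilon_{ij}} to a stand's repeated per-tree counts, where
#' \eqn{a_i \sim N(0, \sigma_A^2)} is a tree-level deviation of the
#' asymptote and \eqn{\epsilon_{ij} \sim N(0, \sigma_e^2)}. Estimation is
#' nonlinear mixed-effects maximum likelihood (restricted by default) via
#' [nlme::nlme()]; starting values come from a deterministic log-log
#' linearisation, with jittered restarts on non-convergence. With fewer
#' than two trees (or if every mixed fit fails) the model falls back to
#' fixed-effects nonlinear least squares with \eqn{\sigma_A = 0}, with a
#' warning.
#'
#' @param observations Long-format observation table (see
#'   [generate_tree()] for the column contract); must contain one stand.
#' @param response Which phase count to model; `"total"` (the default)
#'   fits the cumulative total, `"mature"` the mature-cell count.
#' @param method `"reml"` (restricted ML, default) or `"ml"`.
#' @return An object of class `xylo_fit` with the population parameters
#'   (as [gompertz_params()]), their standard errors and t-values, the
#'   random-effect SD `sigma_A`, residual SD `sigma_e`, conditional modes
#'   of the per-tree deviations, fixed-effects-only R², residual df
#'   (`n_obs - 3`), log-likelihood, and an honest `converged` flag.
#' @seealso [tidy.xylo_fit()], [glance.xylo_fit()],
#'   [predict.xylo_fit()], [compute_r_squared()].
#' @export
fit_stand <- function(observations, response = "total",
                      method = c("reml", "ml")) {
  method <- match.arg(method)
  col <- response_column(response)
  required <- c("tree_id", "doy", col)
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0)
    stop("observations lack required columns: ",
         paste(missing_cols, collapse = ", "))
  d <- data.frame(
    tree_id = factor(observations$tree_id),
    doy = as.numeric(observations$doy),
    y = as.numeric(observations[[col]])
  )
  d <- d[stats::complete.cases(d), ]
  n_trees <- nlevels(droplevels(d$tree_id))
  per_tree <- table(droplevels(d$tree_id))
  if (any(per_tree < 6))
    warning("some trees have fewer than 6 observations; fit may be fragile")

  start <- gompertz_start(d$doy, d$y)
  stand_id <- if ("stand_id" %in% names(observations))
    as.character(observations$stand_id[1]) else NA_character_

  if (n_trees < 2) {
    warning("fewer than 2 trees: falling back to fixed-effects NLS (sigma_A = 0)")
    return(fit_stand_nls(d, start, stand_id, response, method))
  }

  nlme_method <- toupper(method)
  ctrl <- nlme::nlmeControl(maxIter = 200, msMaxIter = 200,
                            pnlsMaxIter = 20, tolerance = 1e-6)
  jitters <- list(c(1, 1, 1), c(1.1, 0.95, 1.1), c(0.9, 1.05, 0.9),
                  c(1.25, 1, 0.8))
  fit <- NULL
  for (j in jitters) {
    st <- start * j
    fit <- tryCatch(
      nlme::nlme(y ~ A * exp(-exp(beta - k * doy)),
                 fixed = A + beta + k ~ 1,
                 random = A ~ 1 | tree_id,
                 data = d, start = st, method = nlme_method, control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    warning("mixed-effects fit failed after restarts: ",
            "falling back to fixed-effects NLS (sigma_A = 0, converged = FALSE)")
    out <- fit_stand_nls(d, start, stand_id, response, method)
    out$converged <- FALSE
    return(out)
  }

  fx <- nlme::fixef(fit)
  sm <- summary(fit)$tTable
  re <- nlme::ranef(fit)
  tree_effects <- stats::setNames(re[["A"]], rownames(re))
  p <- gompertz_params(unname(fx["A"]), unname(fx["beta"]), unname(fx["k"]))
  vc <- nlme::VarCorr(fit)
  sigma_A <- suppressWarnings(as.numeric(vc["A", "StdDev"]))
  structure(list(
    fixed = p,
    std_errors = stats::setNames(sm[, "Std.Error"], rownames(sm)),
    t_values = stats::setNames(sm[, "t-value"], rownames(sm)),
    p_values = stats::setNames(sm[, "p-value"], rownames(sm)),
    sigma_A = sigma_A,
    sigma_e = fit$sigma,
    tree_effects = tree_effects,
    n_obs = nrow(d),
    df = nrow(d) - 3L,
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = TRUE,
    method = method,
    response = response,
    engine = "nlme",
    stand_id = stand_id,
    data = tibble::as_tibble(d),
    r_squared = NA_real_
  ), class = "xylo_fit") |> add_r_squared()
}

fit_stand_nls <- function(d, start, stand_id, response, method) {
  fit <- minpack.lm::nlsLM(y ~ A * exp(-exp(beta - k * doy)),
                           data = d, start = as.list(start),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  p <- gompertz_params(co["A", 1], co["beta", 1], co["k", 1])
  trees <- levels(droplevels(d$tree_id))
  structure(list(
    fixed = p,
    std_errors = stats::setNames(co[, 2], rownames(co)),
    t_values = stats::setNames(co[, 3], rownames(co)),
    p_values = stats::setNames(co[, 4], rownames(co)),
    sigma_A = 0,
    sigma_e = summary(fit)$sigma,
    tree_effects = stats::setNames(rep(0, length(trees)), trees),
    n_obs = nrow(d),
    df = nrow(d) - 3L,
    log_likelihood = as.numeric(stats::logLik(fit)),
    converged = TRUE,
    method = method,
    response = response,
    engine = "nls",
    stand_id = stand_id,
    data = tibble::as_tibble(d),
    r_squared = NA_real_
  ), class = "xylo_fit") |> add_r_squared()
}

add_r_squared <- function(fit) {
  fit$r_squared <- compute_r_squared(fit)
  fit
}

#' Coefficient of determination of a stand fit
#'
#' `1 - SSE/SST` where the sums of squares use population-level
#' (fixed-effects-only) predictions by default; `level = "tree"` instead
#' conditions on the estimated per-tree asymptote deviations. Clamped to
#' \[0, 1\].
#'
#' @param fit An [fit_stand()] result.
#' @param level `"population"` (default) or `"tree"`.
#' @return A fraction in \[0, 1\].
#' @export
compute_r_squared <- function(fit, level = c("population", "tree")) {
  level <- match.arg(level)
  d <- fit$data
  sst <- sum((d$y - mean(d$y))^2)
  if (sst == 0) stop("response has zero variance; R^2 undefined")
  pred <- if (level == "population") {
    gompertz_value(d$doy, fit$fixed)
  } else {
    A_i <- fit$fixed$A + fit$tree_effects[as.character(d$tree_id)]
    A_i * exp(-exp(fit$fixed$beta - fit$fixed$k * d$doy))
  }
  max(0, min(1, 1 - sum((d$y - pred)^2) / sst))
}

#' Predict from a stand fit
#'
#' @param object An [fit_stand()] result.
#' @param doy Day(s) of year at which to predict.
#' @param tree_id Optional tree label; if given, the prediction uses that
#'   tree's conditional asymptote `A + a_i`, otherwise the population `A`.
#' @param ... Unused.
#' @return Predicted cell counts (same length as `doy`).
#' @export
predict.xylo_fit <- function(object, doy, tree_id = NULL, ...) {
  A <- object$fixed$A
  if (!is.null(tree_id)) {
    if (!tree_id %in% names(object$tree_effects))
      stop("unknown tree_id: ", tree_id)
    A <- A + object$tree_effects[[tree_id]]
  }
  A * exp(-exp(object$fixed$beta - object$fixed$k * doy))
}

#' @export
print.xylo_fit <- function(x, ...) {
  cat(sprintf("Gompertz stand fit (%s, %s on '%s' counts)%s\n",
              x$engine, toupper(x$method), x$response,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.na(x$stand_id)) cat(sprintf("  stand: %s\n", x$stand_id))
  cat(sprintf("  A = %.4g (SE %.3g), beta = %.4g (SE %.3g), k = %.4g (SE %.3g)\n",
              x$fixed$A, x$std_errors["A"], x$fixed$beta,
              x$std_errors["beta"], x$fixed$k, x$std_errors["k"]))
  cat(sprintf("  sigma_A = %.4g, sigma_e = %.4g, R^2 = %.3f, n = %d (df %d)\n",
              x$sigma_A, x$sigma_e, x$r_squared, x$n_obs, x$df))
  invisible(x)
}

#' Tidy a stand fit into a parameter table
#'
#' One row per fixed parameter with estimate, standard error, residual df,
#' t-value and p-value — the conventional per-stand Gompertz reporting
#' shape.
#'
#' @param x An [fit_stand()] result.
#' @param ... Unused.
#' @return A tibble with columns `stand_id`, `term`, `estimate`,
#'   `std.error`, `df`, `statistic`, `p.value`.
#' @export
tidy.xylo_fit <- function(x, ...) {
  terms <- c("A", "beta", "k")
  tibble::tibble(
    stand_id = x$stand_id,
    term = terms,
    estimate = c(x$fixed$A, x$fixed$beta, x$fixed$k),
    std.error = unname(x$std_errors[terms]),
    df = x$df,
    statistic = unname(x$t_values[terms]),
    p.value = unname(x$p_values[terms])
  )
}

#' One-row summary of a stand fit
#'
#' @inheritParams tidy.xylo_fit
#' @return A tibble with `stand_id`, `r.squared`, `sigma_A`, `sigma_e`,
#'   `logLik`, `n_obs`, `df`, `converged`, `method`, `engine`.
#' @export
glance.xylo_fit <- function(x, ...) {
  tibble::tibble(
    stand_id = x$stand_id,
    r.squared = x$r_squared,
    sigma_A = x$sigma_A,
    sigma_e = x$sigma_e,
    logLik = x$log_likelihood,
    n_obs = x$n_obs,
    df = x$df,
    converged = x$converged,
    method = x$method,
    engine = x$engine
  )
}
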