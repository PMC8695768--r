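#' Configuration for an end-to-end wood-formation study analysis
#'
#' Exactly one of `input` (a path to a long-format observation CSV) or
#' `scenarios` (a list of [stand_scenario()]s to simulate) must be given.
#'
#' @param input Path to a CSV with the observation columns of
#'   [generate_tree()].
#' @param scenarios List of [stand_scenario()] objects to simulate
#'   instead of reading data.
#' @param span Smoothing span for trajectory smoothing.
#' @param min_prominence Peak prominence threshold (cells) for seasonal
#'   extrema.
#' @param method Mixed-model estimation: `"reml"` or `"ml"`.
#' @param rate_def Per-tree rate definition feeding the rate--duration
#'   model: `"mean"` (average rate over the 5--95% window, default) or
#'   `"max"` (maximal rate).
#' @param reference_year Calendar year of monitoring, used to derive stand
#'   age from `planting_year`.
#' @param out_dir Optional directory to write the report files into.
#' @param seed Integer seed (used only when simulating).
#' @return A `study_config` object.
#' @export
study_config <- function(input = NULL, scenarios = NULL,
                         span = 0.25, min_prominence = 0.5,
                         method = c("reml", "ml"),
                         rate_def = c("mean", "max"),
                         reference_year = 2019,
                         out_dir = NULL, seed = 1) {
  if (is.null(input) == is.null(scenarios))
    stop("set exactly one of `input` and `scenarios`")
  structure(list(
    input = input, scenarios = scenarios,
    span = span, min_prominence = min_prominence,
    method = match.arg(method), rate_def = match.arg(rate_def),
    reference_year = reference_year,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "study_config")
}

observation_cols <- c("tree_id", "stand_id", "planting_year", "doy",
                      "n_cambial", "n_enlarging", "n_thickening",
                      "n_mature", "n_total")

#' Validate a long-format observation table
#'
#' Checks column presence, day-of-year range (1--366), non-negative
#' integer counts, the total-equals-sum-of-phases identity, and per-tree
#' sampling gaps no wider than 21 days (three times the widest customary
#' micro-coring interval). Reports issues; never throws.
#'
#' @param data Parsed observation table.
#' @return A tibble of issues (`row`, `tree_id`, `doy`, `issue`); zero
#'   rows when the table is clean.
#' @export
validate_input <- function(data) {
  issue <- function(row, tree_id, doy, what) {
    tibble::tibble(row = row, tree_id = tree_id, doy = doy, issue = what)
  }
  issues <- list()
  missing_cols <- setdiff(observation_cols, names(data))
  if (length(missing_cols) > 0) {
    return(issue(NA_integer_, NA_character_, NA_real_,
                 paste("missing columns:", paste(missing_cols, collapse = ", "))))
  }
  bad_doy <- which(!is.finite(data$doy) | data$doy < 1 | data$doy > 366)
  for (i in bad_doy)
    issues <- c(issues, list(issue(i, data$tree_id[i], data$doy[i],
                                   "doy outside 1-366")))
  count_cols <- c("n_cambial", "n_enlarging", "n_thickening", "n_mature",
                  "n_total")
  for (cc in count_cols) {
    v <- data[[cc]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    for (i in bad)
      issues <- c(issues, list(issue(i, data$tree_id[i], data$doy[i],
                                     paste(cc, "not a non-negative integer"))))
  }
  phsum <- data$n_cambial + data$n_enlarging + data$n_thickening + data$n_mature
  bad_sum <- which(is.finite(phsum) & is.finite(data$n_total) &
                     data$n_total != phsum)
  for (i in bad_sum)
    issues <- c(issues, list(issue(
      i, data$tree_id[i], data$doy[i],
      sprintf("n_total (%g) != sum of phases (%g)", data$n_total[i], phsum[i]))))
  gaps <- data |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::arrange(.data$doy, .by_group = TRUE) |>
    dplyr::summarise(max_gap = if (dplyr::n() < 2) 0 else max(diff(.data$doy)),
                     .groups = "drop") |>
    dplyr::filter(.data$max_gap > 21)
  for (i in seq_len(nrow(gaps)))
    issues <- c(issues, list(issue(
      NA_integer_, gaps$tree_id[i], NA_real_,
      sprintf("sampling gap of %g days exceeds 21", gaps$max_gap[i]))))
  if (length(issues) == 0) {
    tibble::tibble(row = integer(), tree_id = character(),
                   doy = numeric(), issue = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

read_observations <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("failed to parse CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(data) == 0) stop("input file '", path, "' contains no observations")
  data
}

per_tree_quantities <- function(observations, fit, phen, rate_def,
                                reference_year) {
  finals <- observations |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::summarise(final_cells = max(.data$n_total), .groups = "drop")
  eff <- tibble::tibble(tree_id = names(fit$tree_effects),
                        a_i = unname(fit$tree_effects))
  phen |>
    dplyr::left_join(finals, by = "tree_id") |>
    dplyr::left_join(eff, by = "tree_id") |>
    dplyr::mutate(
      a_i = dplyr::coalesce(.data$a_i, 0),
      A_tree = fit$fixed$A + .data$a_i,
      r_max = fit$fixed$k * .data$A_tree / exp(1),
      r_m = rm_from_rmax(.data$r_max),
      rate = if (rate_def == "mean") .data$r_m else .data$r_max,
      t_p = inflection_point(fit$fixed),
      age = reference_year - .data$planting_year
    )
}

#' Run the full intra-annual wood-formation analysis
#'
#' End-to-end orchestration: simulate (or read and validate) a long-format
#' observation table, fit the random-asymptote Gompertz model per stand,
#' derive kinetics, detect phenology and within-season extrema, test age
#' trends, fit the rate--duration model and decompose its R² by LMG. The
#' whole run is deterministic given `(input or scenarios, config, seed)`.
#'
#' @param config A [study_config()].
#' @return A named list of report tibbles: `fits` (per-stand parameter
#'   table), `fit_quality`, `extrema` (per-phase seasonal extrema by
#'   stand), `kinetics` (per-stand rate kinetics plus phenology),
#'   `age_anova`, `rate_duration`, `importance`, `per_tree`, and
#'   `manifest`. If `config$out_dir` is set, each is also written as TSV
#'   (`table2.tsv` ... `table6.tsv`, `importance.tsv`) along with
#'   `manifest.json`.
#' @export
run_study <- function(config) {
  if (!inherits(config, "study_config")) stop("`config` must be a study_config")
  observations <- if (!is.null(config$input)) {
    read_observations(config$input)
  } else {
    generate_study(config$scenarios, seed = config$seed)
  }
  issues <- validate_input(observations)
  if (nrow(issues) > 0 && any(grepl("missing columns", issues$issue)))
    stop("malformed input: ", issues$issue[1])

  stands <- split(observations, observations$stand_id)
  stands <- stands[order(-vapply(stands, function(d) d$planting_year[1],
                                 numeric(1)))]

  fit_rows <- list(); quality_rows <- list(); kin_rows <- list()
  extrema_rows <- list(); per_tree_rows <- list(); notes <- character()

  for (sid in names(stands)) {
    obs <- stands[[sid]]
    n_trees <- length(unique(obs$tree_id))
    if (n_trees < 2)
      notes <- c(notes, sprintf("stand %s has %d tree(s): NLS fallback", sid,
                                n_trees))
    fit <- withCallingHandlers(
      fit_stand(obs, response = "total", method = config$method),
      warning = function(w) {
        notes <<- c(notes, sprintf("stand %s: %s", sid, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    fit_rows[[sid]] <- tidy(fit)
    quality_rows[[sid]] <- glance(fit)

    phen <- tree_phenology(obs, phase = "enlarging")
    ps <- stand_phenology(phen)
    kin <- kinetic_summary(fit$fixed)
    kin_rows[[sid]] <- tibble::tibble(
      stand_id = sid,
      planting_year = obs$planting_year[1],
      sample_size = fit$n_obs,
      t_p = kin$t_p, r_max = kin$r_max, r_m = kin$r_m,
      onset = ps$onset_mean, onset_sd = ps$onset_sd,
      end = ps$end_mean, end_sd = ps$end_sd,
      duration = ps$duration_mean, duration_sd = ps$duration_sd
    )
    for (ph in c("cambial", "enlarging", "thickening")) {
      ext <- phase_extrema(obs, phase = ph, span = config$span,
                           min_prominence = config$min_prominence)
      extrema_rows[[paste(sid, ph)]] <- ext$stand
    }
    per_tree_rows[[sid]] <- per_tree_quantities(
      obs, fit, phen, config$rate_def, config$reference_year)
  }

  per_tree <- dplyr::bind_rows(per_tree_rows) |>
    dplyr::filter(!.data$no_growth)
  anova_for <- function(col) {
    age_trend_anova(per_tree, !!rlang::sym(col), "age")[1, ] |>
      dplyr::mutate(response = col, .before = 1)
  }
  age_anova <- dplyr::bind_rows(lapply(
    c("final_cells", "onset_doy", "end_doy", "duration_days",
      "t_p", "r_max", "r_m"), anova_for))

  rd_fit <- fit_rate_duration(per_tree, "final_cells", "rate",
                              "duration_days")
  rate_duration <- tidy(rd_fit)
  imp <- lmg_importance(rd_fit)
  importance <- tidy(imp) |>
    dplyr::mutate(percent = 100 * .data$lmg_normalized)

  manifest <- list(
    package = "xylodyn",
    version = as.character(utils::packageVersion("xylodyn")),
    seed = config$seed,
    config = list(
      input = config$input %||% "simulated",
      n_scenarios = length(config$scenarios),
      span = config$span, min_prominence = config$min_prominence,
      method = config$method, rate_def = config$rate_def,
      reference_year = config$reference_year
    ),
    n_observations = nrow(observations),
    n_stands = length(stands),
    converged = vapply(quality_rows, function(g) g$converged, logical(1)),
    validation_issues = nrow(issues),
    notes = notes
  )

  reports <- list(
    fits = dplyr::bind_rows(fit_rows),
    fit_quality = dplyr::bind_rows(quality_rows),
    extrema = dplyr::bind_rows(extrema_rows),
    kinetics = dplyr::bind_rows(kin_rows),
    age_anova = age_anova,
    rate_duration = rate_duration,
    importance = importance,
    per_tree = per_tree,
    observations = observations,
    validation = issues,
    manifest = manifest
  )

  if (!is.null(config$out_dir)) write_reports(reports, config$out_dir)
  reports
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_reports <- function(reports, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(fits = "table2.tsv", extrema = "table3.tsv",
             kinetics = "table4.tsv", age_anova = "table5.tsv",
             rate_duration = "table6.tsv", importance = "importance.tsv",
             fit_quality = "fit_quality.tsv", per_tree = "per_tree.tsv")
  for (nm in names(files)) {
    readr::write_tsv(reports[[nm]], file.path(out_dir, files[[nm]]))
  }
  jsonlite::write_json(reports$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
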