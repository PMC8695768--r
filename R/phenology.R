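#' Onset, end and duration of wood cell development for one tree
#'
#' Applies the enlargement-phase rule: development starts at the first
#' sampling day whose (row-averaged) enlarging-cell count exceeds the
#' threshold — i.e. at least one row of cells seen enlarging — and ends at
#' the last such day. Onset and end are assigned to observed sampling days;
#' no interpolation is done between collections.
#'
#' @param doy Sampled days of year, sorted increasing.
#' @param count Enlarging-cell counts at `doy` (non-negative).
#' @param threshold Count strictly above which the phase is "present"
#'   (default 0: any cell in any row).
#' @return A one-row tibble with `onset_doy`, `end_doy`, `duration_days`
#'   and a logical `no_growth` flag; an all-zero series yields `NA` timings
#'   with `no_growth = TRUE` rather than an error.
#' @export
detect_onset_end <- function(doy, count, threshold = 0) {
  stopifnot(length(doy) == length(count))
  if (is.unsorted(doy)) stop("`doy` must be sorted increasing")
  if (any(count < 0)) stop("counts must be non-negative")
  active <- which(count > threshold)
  if (length(active) == 0) {
    return(tibble::tibble(onset_doy = NA_real_, end_doy = NA_real_,
                          duration_days = NA_real_, no_growth = TRUE))
  }
  onset <- doy[min(active)]
  end <- doy[max(active)]
  tibble::tibble(onset_doy = onset, end_doy = end,
                 duration_days = end - onset, no_growth = FALSE)
}

#' Per-tree phenology for a whole observation table
#'
#' Maps [detect_onset_end()] over every tree in a long-format observation
#' table.
#'
#' @param observations Observation table with `tree_id`, `doy` and the
#'   phase count columns of [generate_tree()].
#' @param phase Phase whose presence defines the growing period
#'   (`"enlarging"`, the conventional choice).
#' @param threshold Passed to [detect_onset_end()].
#' @return A tibble with one row per tree: `tree_id`, `stand_id` (if
#'   present), `onset_doy`, `end_doy`, `duration_days`, `no_growth`.
#' @export
tree_phenology <- function(observations, phase = "enlarging", threshold = 0) {
  col <- response_column(phase)
  keys <- intersect(c("tree_id", "stand_id", "planting_year"),
                    names(observations))
  observations |>
    dplyr::arrange(.data$doy) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe(detect_onset_end(.data$doy, .data[[col]], threshold))
}

#' Stand-level phenology summary
#'
#' Arithmetic mean and sample SD of onset, end and duration over the trees
#' of a stand. By linearity the mean duration always equals mean end minus
#' mean onset. Trees flagged `no_growth` are dropped. With a single tree
#' the SDs are reported as 0 and `sd_defined` is `FALSE`.
#'
#' @param records Per-tree phenology tibble from [tree_phenology()].
#' @return A one-row tibble (or one row per stand if `stand_id` is
#'   present) with `n_trees`, mean and SD of onset/end/duration, and
#'   `sd_defined`.
#' @export
stand_phenology <- function(records) {
  if (nrow(records) == 0) stop("no phenology records")
  records <- dplyr::filter(records, !.data$no_growth)
  if (nrow(records) == 0) stop("all trees flagged no_growth")
  keys <- intersect(c("stand_id", "planting_year"), names(records))
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      onset_mean = mean(.data$onset_doy), onset_sd = sd0(.data$onset_doy),
      end_mean = mean(.data$end_doy), end_sd = sd0(.data$end_doy),
      duration_mean = mean(.data$duration_days),
      duration_sd = sd0(.data$duration_days),
      sd_defined = dplyr::n() >= 2,
      .groups = "drop"
    )
}

#' Smooth a phase trajectory on its sampling grid
#'
#' Local linear regression with tricube weights (loess, degree 1)
#' evaluated back at every observed day of year; deterministic and
#' length-preserving. Reproduces constants and straight lines exactly (to
#' numerical tolerance), which makes it a safe pre-filter for extrema
#' detection on noisy count series.
#'
#' @param doy Sampled days of year (>= 7 points).
#' @param count Counts at `doy`.
#' @param span Smoothing span as the fraction of points in each local
#'   window, in (0, 1]; default 0.25 resolves within-season bumps roughly
#'   120 days apart without chasing sampling noise.
#' @return Numeric vector of smoothed values, same length as `doy`.
#' @export
smooth_series <- function(doy, count, span = 0.25) {
  if (length(doy) < 7) stop("need at least 7 points to smooth")
  if (span <= 0 || span > 1) stop("`span` must lie in (0, 1]")
  stopifnot(length(doy) == length(count))
  # loess needs enough points in each window for a degree-1 fit
  span <- max(span, 3.5 / length(doy))
  fit <- stats::loess(count ~ doy, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, newdata = data.frame(doy = doy)))
}

# Topographic prominence of local maximum `i` among candidates on a grid:
# on each side, walk to the nearest strictly higher point (or the series
# boundary) and record the minimum along the way; prominence is the peak
# height above the higher of the two side minima.
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- -Inf   # boundary peak: prominence judged on the open side only
  if (i > 1) {
    j <- i - 1
    left_min <- y[j]
    while (j >= 1 && y[j] <= y[i]) {
      left_min <- min(left_min, y[j]); j <- j - 1
    }
    if (j < 1) left_min <- min(y[1:i])
  }
  right_min <- y[i]
  if (i < n) {
    j <- i + 1
    right_min <- y[j]
    while (j <= n && y[j] <= y[i]) {
      right_min <- min(right_min, y[j]); j <- j + 1
    }
    if (j > n) right_min <- min(y[i:n])
  }
  y[i] - max(left_min, right_min)
}

local_max_candidates <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  if (y[1] > y[2]) idx <- c(idx, 1L)       # left boundary maximum
  for (i in 2:(n - 1)) {
    if (y[i] >= y[i - 1] && y[i] > y[i + 1]) idx <- c(idx, i)
  }
  idx
}

#' Within-season extrema of a (smoothed) phase trajectory
#'
#' Identifies interior local maxima by sign changes of discrete
#' differences (the series' first point is eligible as a boundary maximum,
#' as dormant-season cambial counts often start at their annual maximum),
#' keeps those with topographic prominence at or above `min_prominence`,
#' and labels the two most prominent, in day-of-year order, as the first
#' and second seasonal maxima. The first minimum is the lowest point
#' between them and the second minimum the lowest point after the second
#' maximum (the last sample is eligible). Equal-height candidates resolve
#' to the earliest day.
#'
#' @param doy Sampled days of year.
#' @param count Smoothed counts at `doy` (see [smooth_series()]).
#' @param min_prominence Minimum prominence (cells) for a maximum to count
#'   as a seasonal peak; default 0.5.
#' @return A one-row tibble with `pattern` (`"bimodal"`, `"unimodal"` or
#'   `"none"`), the four extrema as `first_max_doy`/`first_max_cells`,
#'   `first_min_doy`/`first_min_cells`, `second_max_doy`/
#'   `second_max_cells`, `second_min_doy`/`second_min_cells` (unimodal
#'   series fill only the single max and the post-peak min; monotone
#'   series fill nothing), plus flags `second_lower` (second maximum not
#'   above the first, the typical field pattern) and `ambiguous` (more
#'   than two prominent maxima were found and the two most prominent were
#'   kept).
#' @export
find_bimodal_extrema <- function(doy, count, min_prominence = 0.5) {
  stopifnot(length(doy) == length(count))
  if (is.unsorted(doy)) stop("`doy` must be sorted increasing")
  n <- length(count)
  empty <- tibble::tibble(
    pattern = "none",
    first_max_doy = NA_real_, first_max_cells = NA_real_,
    first_min_doy = NA_real_, first_min_cells = NA_real_,
    second_max_doy = NA_real_, second_max_cells = NA_real_,
    second_min_doy = NA_real_, second_min_cells = NA_real_,
    second_lower = NA, ambiguous = FALSE
  )
  cand <- local_max_candidates(count)
  if (length(cand) == 0) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(count, i), numeric(1))
  keep <- cand[prom >= min_prominence]
  prom <- prom[prom >= min_prominence]
  if (length(keep) == 0) return(empty)

  lowest_between <- function(from, to) {
    idx <- which(doy > doy[from] & doy <= doy[to])
    idx[which.min(count[idx])]
  }
  lowest_after <- function(from) {
    idx <- which(doy > doy[from])
    if (length(idx) == 0) return(NA_integer_)
    idx[which.min(count[idx])]
  }

  if (length(keep) == 1) {
    i <- keep[1]
    j <- lowest_after(i)
    out <- empty
    out$pattern <- "unimodal"
    out$first_max_doy <- doy[i]; out$first_max_cells <- count[i]
    if (!is.na(j)) {
      out$second_min_doy <- doy[j]; out$second_min_cells <- count[j]
    }
    return(out)
  }

  ambiguous <- length(keep) > 2
  # two most prominent (ties: taller, then earlier), then DOY order
  ord <- order(-prom, -count[keep], doy[keep])
  top2 <- sort(keep[ord[1:2]])
  i1 <- top2[1]; i2 <- top2[2]
  imin1 <- lowest_between(i1, i2)
  imin2 <- lowest_after(i2)
  tibble::tibble(
    pattern = "bimodal",
    first_max_doy = doy[i1], first_max_cells = count[i1],
    first_min_doy = doy[imin1], first_min_cells = count[imin1],
    second_max_doy = doy[i2], second_max_cells = count[i2],
    second_min_doy = if (is.na(imin2)) NA_real_ else doy[imin2],
    second_min_cells = if (is.na(imin2)) NA_real_ else count[imin2],
    second_lower = count[i2] <= count[i1],
    ambiguous = ambiguous
  )
}

#' Per-tree seasonal extrema of a phase, summarised by stand
#'
#' Smooths each tree's trajectory of the requested phase, runs
#' [find_bimodal_extrema()], and summarises extremum timings and heights
#' (mean and SD over trees) per stand — the conventional per-phase
#' seasonal-extrema reporting shape.
#'
#' @inheritParams tree_phenology
#' @param phase Phase column to analyse (`"cambial"`, `"enlarging"`,
#'   `"thickening"`, ...).
#' @param span Smoothing span, see [smooth_series()].
#' @param min_prominence See [find_bimodal_extrema()].
#' @return A list with `trees` (one extrema row per tree) and `stand`
#'   (per-stand mean/SD of each extremum's DOY and cell count, with the
#'   count of trees classified per pattern).
#' @export
phase_extrema <- function(observations, phase = "enlarging", span = 0.25,
                          min_prominence = 0.5) {
  col <- response_column(phase)
  keys <- intersect(c("tree_id", "stand_id", "planting_year"),
                    names(observations))
  trees <- observations |>
    dplyr::arrange(.data$doy) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::reframe({
      sm <- smooth_series(.data$doy, .data[[col]], span = span)
      find_bimodal_extrema(.data$doy, sm, min_prominence = min_prominence)
    }) |>
    dplyr::mutate(phase = phase, .before = 1)

  skeys <- intersect(c("stand_id", "planting_year"), names(trees))
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sd_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::sd(x)
  }
  stand <- trees |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("phase", skeys)))) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      n_bimodal = sum(.data$pattern == "bimodal"),
      dplyr::across(dplyr::ends_with("_doy") | dplyr::ends_with("_cells"),
                    list(mean = mean_na, sd = sd_na)),
      .groups = "drop"
    )
  list(trees = trees, stand = stand)
}
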