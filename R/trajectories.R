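#' Build overlapping age windows
#'
#' Windows of `width` years starting every `step` years, so consecutive
#' windows overlap by `width - step` years. The defaults (5-year windows
#' advancing by 1 year from age 6 to 26) give the 21 windows
#' "6 to 10" through "26 to 30" used for smooth cross-sectional
#' developmental trajectories.
#'
#' @param min_lo First window start (integer years).
#' @param max_lo Last window start (integer years).
#' @param width Window width in years.
#' @param step Advance between consecutive windows in years.
#' @return A tibble with columns `index`, `lo`, `width`, `label`.
#' @export
build_age_windows <- function(min_lo = 6L, max_lo = 26L, width = 5L, step = 1L) {
  vals <- c(min_lo = min_lo, max_lo = max_lo, width = width, step = step)
  if (any(!is.finite(vals)) || any(vals != round(vals)) ||
      width < 1 || step < 1 || min_lo < 0 || max_lo < min_lo ||
      (max_lo - min_lo) %% step != 0) {
    abort("Window parameters must be non-negative integers with max_lo >= min_lo and (max_lo - min_lo) divisible by step.",
          class = "entrajectory_parameter_error")
  }
  lo <- seq(as.integer(min_lo), as.integer(max_lo), by = as.integer(step))
  tibble::tibble(
    index = seq_along(lo),
    lo = lo,
    width = as.integer(width),
    label = sprintf("%d to %d", lo, lo + as.integer(width) - 1L)
  )
}

#' Assign subjects to every age window containing them
#'
#' A subject of age `a` belongs to every window with `lo <= a < lo + width`,
#' on continuous (possibly fractional) age. Under the labelling convention
#' the window "26 to 30" therefore admits ages up to (but excluding) 31.
#' Subjects falling in no window are reported in the `unassigned` attribute
#' and via a message, never dropped silently.
#'
#' @param subjects Tibble with columns `subject_id` and `age`.
#' @param windows Output of [build_age_windows()].
#' @return A tibble with columns `subject_id`, `window_index`; attribute
#'   `unassigned` holds the ids of subjects outside all windows.
#' @export
assign_to_windows <- function(subjects, windows) {
  membership <- tidyr::crossing(
    subjects |> dplyr::select("subject_id", "age"),
    windows |> dplyr::select(window_index = "index", "lo", "width")
  ) |>
    dplyr::filter(.data$age >= .data$lo, .data$age < .data$lo + .data$width) |>
    dplyr::select("subject_id", "window_index") |>
    dplyr::arrange(.data$subject_id, .data$window_index)
  unassigned <- setdiff(subjects$subject_id, membership$subject_id)
  if (length(unassigned) > 0L) {
    inform(sprintf("%d subject(s) fall outside all age windows: %s",
                   length(unassigned), paste(head(unassigned, 10L), collapse = ", ")))
  }
  attr(membership, "unassigned") <- unassigned
  membership
}

#' One-sample Kolmogorov-Smirnov check against a fitted normal
#'
#' Compares the sample to a normal distribution with the sample's own mean
#' and SD. This is reported per window-by-group cell for distributional
#' context only; it never gates the parametric group test.
#'
#' @param values Numeric sample (at least 5 finite values).
#' @return A tibble with columns `statistic`, `p_value`, `n`; both statistics
#'   are `NA` (with a warning) when fewer than 5 values are available.
#' @export
ks_normality <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 5L) {
    warn("Kolmogorov-Smirnov check skipped: fewer than 5 values.")
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_, n = length(x)))
  }
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  tibble::tibble(statistic = unname(kt$statistic), p_value = kt$p.value, n = length(x))
}

#' Generalized extreme studentized deviate (GESD) outlier test
#'
#' Rosner's procedure for up to `max_k` outliers in an approximately normal
#' sample: iteratively remove the point with the largest studentized
#' absolute deviation, compare each test statistic R_i against its critical
#' value lambda_i from the t distribution, and declare the largest `i` with
#' R_i > lambda_i points as outliers.
#'
#' @param values Numeric sample.
#' @param max_k Maximum number of outliers tested; default one tenth of the
#'   sample size (at least 1).
#' @param alpha Significance level of the test.
#' @return Integer vector of outlier positions in `values` (possibly empty).
#' @export
gesd_outliers <- function(values, max_k = max(1L, ceiling(0.1 * length(values))),
                          alpha = 0.05) {
  x <- as.numeric(values)
  n <- length(x)
  if (max_k < 1L) abort("`max_k` must be at least 1.", class = "entrajectory_parameter_error")
  if (n < max_k + 3L) {
    abort(sprintf("GESD needs at least max_k + 3 = %d observations, got %d.", max_k + 3L, n),
          class = "entrajectory_parameter_error")
  }
  remaining <- seq_len(n)
  removed <- integer(0)
  r_stat <- lambda <- rep(NA_real_, max_k)
  for (i in seq_len(max_k)) {
    xi <- x[remaining]
    s <- sd(xi)
    if (!is.finite(s) || s == 0) break
    dev <- abs(xi - mean(xi))
    j <- which.max(dev)
    r_stat[i] <- dev[j] / s
    ni <- length(xi)
    p <- 1 - alpha / (2 * ni)
    tq <- qt(p, ni - 2L)
    lambda[i] <- (ni - 1) * tq / sqrt((ni - 2L + tq^2) * ni)
    removed <- c(removed, remaining[j])
    remaining <- remaining[-j]
  }
  tested <- which(!is.na(r_stat))
  n_out <- if (length(tested) > 0L && any(r_stat[tested] > lambda[tested])) {
    max(tested[r_stat[tested] > lambda[tested]])
  } else 0L
  removed[seq_len(n_out)]
}

# Long per-cell subject values after optional GESD screening.
# One row per (window, group, unit, region, subject); `outlier` marks values
# flagged by GESD within their cell. Screening is skipped (nothing flagged)
# in cells too small for the test.
screened_cell_values <- function(profiles, membership, subjects,
                                 gesd_alpha = 0.05, gesd_max_k = NULL,
                                 screen = TRUE) {
  long <- tibble::as_tibble(profiles) |>
    dplyr::inner_join(subjects |> dplyr::select("subject_id", "group"),
                      by = "subject_id") |>
    dplyr::inner_join(membership, by = "subject_id",
                      relationship = "many-to-many")
  long |>
    dplyr::group_by(.data$window_index, .data$group, .data$unit, .data$region_id) |>
    dplyr::group_modify(function(d, key) {
      d$outlier <- FALSE
      ok <- which(is.finite(d$entropy))
      if (screen && length(ok) >= 4L) {
        k <- if (is.null(gesd_max_k)) max(1L, ceiling(0.1 * length(ok))) else gesd_max_k
        k <- min(k, length(ok) - 3L)
        if (k >= 1L) {
          out <- gesd_outliers(d$entropy[ok], max_k = k, alpha = gesd_alpha)
          d$outlier[ok[out]] <- TRUE
        }
      }
      d
    }) |>
    dplyr::ungroup()
}

#' Group trajectories of regional and whole-brain entropy
#'
#' For every window-by-group cell, applies GESD outlier screening within the
#' cell and summarizes the surviving subjects' entropy values. Conventions:
#' a single-subject cell reports SD 0 and a missing SEM; an empty cell
#' reports n = 0 with missing mean.
#'
#' @param profiles Stacked [regional_profile()] rows for the cohort.
#' @param membership Output of [assign_to_windows()].
#' @param subjects Tibble with `subject_id`, `group`.
#' @param gesd_alpha,gesd_max_k GESD parameters; `NULL` `gesd_max_k` means
#'   one tenth of the cell size (at least 1).
#' @param screen Set `FALSE` to skip outlier screening.
#' @return A tibble of class `trajectory_table`: `window_index`, `group`,
#'   `unit`, `region_id`, `mean`, `sd`, `sem`, `n`, `n_outliers_removed`,
#'   plus the cell's normality check (`ks_statistic`, `ks_p`).
#' @export
group_trajectory <- function(profiles, membership, subjects,
                             gesd_alpha = 0.05, gesd_max_k = NULL,
                             screen = TRUE) {
  cells <- screened_cell_values(profiles, membership, subjects,
                                gesd_alpha, gesd_max_k, screen)
  out <- cells |>
    dplyr::group_by(.data$window_index, .data$group, .data$unit, .data$region_id) |>
    dplyr::group_modify(function(d, key) {
      vals <- d$entropy[is.finite(d$entropy) & !d$outlier]
      n <- length(vals)
      ks <- if (n >= 5L) ks_normality(vals) else
        tibble::tibble(statistic = NA_real_, p_value = NA_real_)
      tibble::tibble(
        mean = if (n > 0L) mean(vals) else NA_real_,
        sd = if (n > 1L) sd(vals) else if (n == 1L) 0 else NA_real_,
        sem = if (n > 1L) sd(vals) / sqrt(n) else NA_real_,
        n = n,
        n_outliers_removed = sum(d$outlier),
        ks_statistic = ks$statistic[1],
        ks_p = ks$p_value[1]
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$unit, .data$region_id, .data$window_index, .data$group)
  class(out) <- c("trajectory_table", class(out))
  out
}

#' Two-sided independent-samples t test for one window cell
#'
#' Pooled-variance (Student) by default, matching the classical reading of
#' an independent t test; set `var_equal = FALSE` for the Welch variant.
#'
#' @param case_values,control_values Numeric samples, each with at least 2
#'   values and nonzero pooled variance.
#' @param var_equal Pool variances (default) or use Welch's correction.
#' @return A tibble with `t`, `df`, `p_value`, `n_case`, `n_control`;
#'   all-`NA` statistics (with a warning) for degenerate inputs.
#' @export
window_ttest <- function(case_values, control_values, var_equal = TRUE) {
  x <- case_values[is.finite(case_values)]
  y <- control_values[is.finite(control_values)]
  skip <- function() {
    warn("t test skipped: need n >= 2 per group and nonzero pooled variance.")
    tibble::tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                   n_case = length(x), n_control = length(y))
  }
  if (length(x) < 2L || length(y) < 2L) return(skip())
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      # identical samples: no evidence of a difference by convention
      return(tibble::tibble(t = 0, df = length(x) + length(y) - 2,
                            p_value = 1, n_case = length(x), n_control = length(y)))
    }
    return(skip())
  }
  tt <- t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, n_case = length(x), n_control = length(y))
}

#' Bonferroni-corrected significance level
#'
#' @param base_alpha Uncorrected significance level.
#' @param n_comparisons Number of comparisons in the family.
#' @return `base_alpha / n_comparisons`.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, n_comparisons) {
  if (!is.numeric(n_comparisons) || length(n_comparisons) != 1L || n_comparisons < 1) {
    abort("`n_comparisons` must be at least 1.", class = "entrajectory_parameter_error")
  }
  base_alpha / n_comparisons
}

#' Group tests across all windows and units
#'
#' Runs the per-cell independent t test between case and control survivors
#' of the GESD screening, for the whole brain and every region, in every
#' window. Because consecutive windows overlap, each subject recurs in
#' `width / step` windows; the Bonferroni family size is that overlap
#' factor for the whole-brain family and overlap times the number of
#' regions for the regional family (0.05/5 = 0.01 and 0.05/450
#' respectively at the defaults).
#'
#' @inheritParams group_trajectory
#' @param windows Output of [build_age_windows()] (used for the overlap
#'   factor).
#' @param base_alpha Uncorrected significance level.
#' @param var_equal Passed to [window_ttest()].
#' @return A tibble of class `group_test_table` with `t`, `df`, `p_value`,
#'   `corrected_alpha`, `significant` per (window, unit, region).
#' @export
window_group_tests <- function(profiles, membership, subjects, windows,
                               base_alpha = 0.05, gesd_alpha = 0.05,
                               gesd_max_k = NULL, screen = TRUE,
                               var_equal = TRUE) {
  cells <- screened_cell_values(profiles, membership, subjects,
                                gesd_alpha, gesd_max_k, screen)
  win_step <- if (nrow(windows) >= 2L) windows$lo[2] - windows$lo[1] else windows$width[1]
  overlap <- max(1L, windows$width[1] %/% win_step)
  n_regions <- length(unique(cells$region_id[cells$unit == "region"]))
  out <- cells |>
    dplyr::filter(!.data$outlier, is.finite(.data$entropy)) |>
    dplyr::group_by(.data$window_index, .data$unit, .data$region_id) |>
    dplyr::group_modify(function(d, key) {
      suppressWarnings(window_ttest(d$entropy[d$group == "case"],
                                    d$entropy[d$group == "control"],
                                    var_equal = var_equal))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      corrected_alpha = dplyr::if_else(
        .data$unit == "whole_brain",
        bonferroni_alpha(base_alpha, overlap),
        bonferroni_alpha(base_alpha, overlap * max(n_regions, 1L))
      ),
      significant = !is.na(.data$p_value) & .data$p_value < .data$corrected_alpha
    )
  class(out) <- c("group_test_table", class(out))
  out
}

#' Differential complexity curves (case minus control)
#'
#' For every unit and window, the case-group mean entropy minus the
#' control-group mean; missing whenever either group mean is missing
#' (never silently zero).
#'
#' @param traj A [group_trajectory()] table.
#' @return A tibble of class `differential_curves` with columns `unit`,
#'   `region_id`, `window_index`, `diff`.
#' @export
differential_curves <- function(traj) {
  out <- tibble::as_tibble(traj) |>
    dplyr::select("window_index", "group", "unit", "region_id", "mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean")
  for (g in c("case", "control")) {
    if (!g %in% names(out)) out[[g]] <- NA_real_
  }
  out <- out |>
    dplyr::mutate(diff = .data$case - .data$control) |>
    dplyr::select("unit", "region_id", "window_index", "diff") |>
    dplyr::arrange(.data$unit, .data$region_id, .data$window_index)
  class(out) <- c("differential_curves", class(out))
  out
}

#' Differential curves as a region-by-window matrix
#'
#' @param curves A [differential_curves()] tibble.
#' @param unit Which unit level to extract (default regions).
#' @return A numeric matrix, rows named `region_<id>`, columns
#'   `window_<index>`.
#' @export
curves_matrix <- function(curves, unit = "region") {
  d <- tibble::as_tibble(curves) |> dplyr::filter(.data$unit == !!unit)
  wide <- d |>
    dplyr::mutate(col = sprintf("window_%d", .data$window_index)) |>
    dplyr::select("region_id", "col", "diff") |>
    tidyr::pivot_wider(names_from = "col", values_from = "diff") |>
    dplyr::arrange(.data$region_id)
  m <- as.matrix(wide[-1])
  rownames(m) <- if (unit == "region") sprintf("region_%d", wide$region_id) else "whole_brain"
  m
}
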