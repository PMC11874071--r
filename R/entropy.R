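#' Sample entropy parameters
#'
#' Defaults follow the short-epoch regime of resting-state BOLD series:
#' embedding dimension `m = 1` (valid for series longer than 10^1 samples),
#' tolerance r = 0.15 standard deviations of the (coarse-grained) series,
#' and coarse-graining scale 1 (no coarse-graining).
#'
#' @param m Embedding dimension, a positive integer.
#' @param r_frac Tolerance as a fraction of the series SD, positive.
#' @param scale Coarse-graining factor, a positive integer.
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 1L, r_frac = 0.15, scale = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    abort("`m` must be a positive integer.", class = "entrajectory_parameter_error")
  }
  if (!is.numeric(r_frac) || length(r_frac) != 1L || r_frac <= 0) {
    abort("`r_frac` must be a positive real.", class = "entrajectory_parameter_error")
  }
  if (!is.numeric(scale) || length(scale) != 1L || scale < 1 || scale != round(scale)) {
    abort("`scale` must be a positive integer.", class = "entrajectory_parameter_error")
  }
  structure(list(m = as.integer(m), r_frac = r_frac, scale = as.integer(scale)),
            class = "entropy_params")
}

#' Coarse-grain a series into non-overlapping block means
#'
#' The multiscale-entropy coarse-graining: element `j` of the output is the
#' mean of the `j`-th non-overlapping block of `scale` consecutive samples;
#' a trailing partial block is dropped. `scale = 1` returns the input.
#'
#' @param series Numeric vector.
#' @param scale Positive integer block length.
#' @return Numeric vector of length `floor(length(series) / scale)`.
#' @export
coarse_grain <- function(series, scale = 1L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale < 1 || scale != round(scale)) {
    abort("`scale` must be a positive integer.", class = "entrajectory_parameter_error")
  }
  scale <- as.integer(scale)
  if (length(series) < scale) {
    abort("Series shorter than the coarse-graining scale.",
          class = "entrajectory_length_error")
  }
  if (scale == 1L) return(series)
  n_blocks <- length(series) %/% scale
  colMeans(matrix(series[seq_len(n_blocks * scale)], nrow = scale))
}

#' Sample entropy of a time series
#'
#' SampEn(m, r) = -log(A / B), where `B` counts unordered pairs of distinct
#' m-length templates whose Chebyshev distance is at most
#' r = `r_frac` * sd(series), and `A` counts the same for (m+1)-length
#' templates (self-matches excluded; both counts run over the N - m
#' template start points). Lower values mean a more regular, repetitive
#' signal. Conventions for degenerate inputs: a constant series returns 0
#' (all templates match at every length); when no template pairs match at
#' either length the estimate is undefined and `NA` is returned.
#'
#' @param series Numeric vector.
#' @param params An [entropy_params()] object.
#' @return A non-negative number, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(series, params = entropy_params()) {
  x <- coarse_grain(as.numeric(series), params$scale)
  n <- length(x)
  if (n < params$m + 2L) {
    abort(sprintf("Series of length %d too short for m = %d (need at least m + 2 samples).",
                  n, params$m),
          class = "entrajectory_length_error")
  }
  s <- sd(x)
  if (!is.finite(s)) return(NA_real_)
  if (s == 0) return(0)
  counts <- sampen_counts_cpp(x, params$m, params$r_frac * s)
  a <- counts[1]; b <- counts[2]
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

#' Largest admissible embedding dimension for a given series length
#'
#' Sample entropy requires the series length to exceed 10^m; this returns
#' the largest integer `m` with `10^m < min_series_length`. For the
#' 77-sample shortest epoch of multi-site resting-state BOLD data this
#' gives `m = 1`.
#'
#' @param min_series_length The shortest series length in the data set.
#' @return A positive integer.
#' @export
select_m <- function(min_series_length) {
  if (!is.numeric(min_series_length) || length(min_series_length) != 1L ||
      min_series_length <= 10) {
    abort("`min_series_length` must exceed 10 for any admissible m.",
          class = "entrajectory_parameter_error")
  }
  m <- 1L
  while (10^(m + 1L) < min_series_length) m <- m + 1L
  m
}

#' Regional sample-entropy profile of one subject
#'
#' Computes sample entropy for every masked voxel, averages defined voxel
#' values within each parcellation region, and summarizes the whole brain.
#' By the default convention the whole-brain value is the unweighted mean
#' of the regional means (each region contributes equally regardless of
#' size); `whole_brain = "voxel"` averages over all defined voxels instead.
#'
#' @param vol A [bold_volume()].
#' @param parc A [parcellation()] on the same grid.
#' @param params An [entropy_params()] object.
#' @param whole_brain `"region"` (default) or `"voxel"` weighting.
#' @return A tibble of class `regional_profile` with columns `subject_id`,
#'   `unit` (`"region"` or `"whole_brain"`), `region_id` (`NA` for the whole
#'   brain), `entropy`, `n_voxels_used`, `n_voxels_dropped`. Regions whose
#'   voxels all have undefined entropy get `NA` entropy.
#' @export
regional_profile <- function(vol, parc, params = entropy_params(),
                             whole_brain = c("region", "voxel")) {
  whole_brain <- match.arg(whole_brain)
  if (!identical(dim(vol$data)[1:3], dim(parc$labels))) {
    abort("BOLD volume and parcellation have different spatial shapes.",
          class = "entrajectory_alignment_error")
  }
  n_vox <- prod(dim(vol$data)[1:3])
  flat <- matrix(vol$data, n_vox, vol$n_timepoints)
  labels <- as.integer(parc$labels)
  idx <- which(as.logical(vol$mask) & labels > 0L)
  ent <- rep(NA_real_, n_vox)
  for (i in idx) {
    ent[i] <- sample_entropy(flat[i, ], params)
  }
  region_ids <- sort(parc$region_table$id)
  per_region <- purrr::map_dfr(region_ids, function(rid) {
    vi <- idx[labels[idx] == rid]
    vals <- ent[vi]
    defined <- vals[!is.na(vals)]
    tibble::tibble(
      region_id = rid,
      entropy = if (length(defined) > 0L) mean(defined) else NA_real_,
      n_voxels_used = length(defined),
      n_voxels_dropped = length(vals) - length(defined)
    )
  })
  empty <- per_region$region_id[is.na(per_region$entropy)]
  if (length(empty) > 0L) {
    inform(sprintf("Subject %s: %d region(s) with no defined voxel entropy: %s",
                   vol$subject_id, length(empty),
                   paste(head(empty, 10L), collapse = ", ")))
  }
  wb <- if (whole_brain == "region") {
    mean(per_region$entropy, na.rm = TRUE)
  } else {
    mean(ent[idx], na.rm = TRUE)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(subject_id = vol$subject_id, unit = "region", per_region),
    tibble::tibble(subject_id = vol$subject_id, unit = "whole_brain",
                   region_id = NA_integer_, entropy = wb,
                   n_voxels_used = sum(per_region$n_voxels_used),
                   n_voxels_dropped = sum(per_region$n_voxels_dropped))
  )
  class(out) <- c("regional_profile", class(out))
  out
}

#' Reshape regional profiles to one row per subject
#'
#' @param profiles A tibble of stacked [regional_profile()] rows.
#' @return A wide tibble: `subject_id`, one `region_<id>` column per region,
#'   and `whole_brain`.
#' @export
profiles_to_wide <- function(profiles) {
  prof <- tibble::as_tibble(profiles)
  regions <- prof |>
    dplyr::filter(.data$unit == "region") |>
    dplyr::mutate(col = sprintf("region_%d", .data$region_id)) |>
    dplyr::select("subject_id", "col", "entropy") |>
    tidyr::pivot_wider(names_from = "col", values_from = "entropy")
  wb <- prof |>
    dplyr::filter(.data$unit == "whole_brain") |>
    dplyr::select("subject_id", whole_brain = "entropy")
  dplyr::left_join(regions, wb, by = "subject_id")
}
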