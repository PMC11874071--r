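# Named substreams: every piece of randomness derives from (seed, name) so
# regenerating any stage alone reproduces it exactly.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) %% 7L + 1L))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629)
}

#' Toy block parcellation on a small grid
#'
#' Splits the voxels of a small 3D grid into `n_regions` contiguous blocks
#' of (as near as possible) equal size, labelled 1..n_regions. With 90
#' regions the packaged anatomical region table supplies the names;
#' otherwise synthetic names are generated.
#'
#' @param grid_shape Integer vector of 3 grid extents (default 9 x 9 x 10,
#'   810 voxels, 9 per region).
#' @param n_regions Number of regions (default 90).
#' @return A [parcellation()].
#' @export
make_toy_parcellation <- function(grid_shape = c(9L, 9L, 10L), n_regions = 90L) {
  n_vox <- prod(grid_shape)
  if (n_vox < n_regions) {
    abort(sprintf("Grid of %d voxels cannot hold %d regions.", n_vox, n_regions),
          class = "entrajectory_parameter_error")
  }
  sizes <- rep(n_vox %/% n_regions, n_regions)
  extra <- n_vox %% n_regions
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- array(rep(seq_len(n_regions), times = sizes), dim = grid_shape)
  tab <- if (n_regions == 90L) {
    aal90_region_table()
  } else {
    tibble::tibble(id = seq_len(n_regions),
                   name = sprintf("toy region %d", seq_len(n_regions)),
                   hemisphere = rep_len(c("left", "right"), n_regions))
  }
  parcellation(labels, tab)
}

#' Region classes of the synthetic trajectory templates
#'
#' The generator plants two developmental templates. The "subcortical"
#' class (median/posterior cingulate, hippocampus, postcentral, parietal,
#' paracentral, basal ganglia, thalamus ids) gets the gentle
#' case-minus-control gap curve; every other region gets the steeper
#' "cortical" curve.
#'
#' @param n_regions Number of regions.
#' @return Character vector of length `n_regions`, values `"cortical"` or
#'   `"subcortical"`.
#' @export
region_template_classes <- function(n_regions = 90L) {
  subcortical_ids <- c(33:38, 57:60, 69:78)
  cls <- rep("cortical", n_regions)
  cls[intersect(subcortical_ids, seq_len(n_regions))] <- "subcortical"
  cls
}

# Spline gap templates (case entropy minus control entropy, nats, vs age):
# negative in childhood, peaking positive in adolescence (~14 y), negative
# again in adulthood; the cortical curve is the steeper of the two.
gap_template <- function(ages, class = c("cortical", "subcortical"),
                         gap_scale = 1) {
  class <- match.arg(class)
  anchors_age <- c(6, 10, 14, 18, 22, 26, 30)
  anchors_gap <- if (class == "cortical") {
    c(-0.060, -0.025, 0.070, 0.010, -0.090, -0.050, -0.020)
  } else {
    c(-0.020, -0.008, 0.015, 0.000, -0.015, -0.010, -0.005)
  }
  f <- stats::splinefun(anchors_age, gap_scale * anchors_gap, method = "natural")
  f(ages)
}

# Mean sample entropy (m = 1, r = 0.15 SD, 120 samples) of the generator's
# standardized AR(1) process as a function of the AR coefficient, measured
# once from the process itself (3000 replicates per level). The response is
# flat below phi ~ 0.15 and steepens towards high phi, so gap templates
# specified in entropy units are mapped to coefficients through this curve
# rather than a constant slope.
sampen_phi_response <- function() {
  list(phi = seq(0.15, 0.95, by = 0.05),
       sampen = c(2.4864, 2.4741, 2.4632, 2.4469, 2.4271, 2.4107, 2.3787,
                  2.3494, 2.3201, 2.2833, 2.2324, 2.1741, 2.1039, 2.0180,
                  1.9088, 1.7451, 1.5283))
}

entropy_for_phi <- function(phi) {
  tab <- sampen_phi_response()
  stats::splinefun(tab$phi, tab$sampen, method = "hyman")(pmin(pmax(phi, 0.15), 0.95))
}

phi_for_entropy <- function(target) {
  tab <- sampen_phi_response()
  target <- pmin(pmax(target, min(tab$sampen)), max(tab$sampen))
  stats::splinefun(rev(tab$sampen), rev(tab$phi), method = "hyman")(target)
}

# Control-group AR(1) coefficient vs age: irregularity rises (phi falls)
# monotonically from childhood to adulthood, so entropy increases with age.
# The case coefficient is chosen so the case-minus-control entropy gap
# equals the class's template, via the measured entropy-vs-phi response.
template_phi <- function(age, group, class, gap_scale = 1) {
  age <- pmin(pmax(age, 6), 30)
  phi_ctrl <- 0.85 - 0.25 * (age - 6) / 24
  if (group == "control") {
    phi <- phi_ctrl
  } else {
    phi <- phi_for_entropy(entropy_for_phi(phi_ctrl) +
                             gap_template(age, class, gap_scale))
  }
  pmin(pmax(phi, 0), 0.95)
}

#' Synthetic cohort specification
#'
#' All generation is a pure function of `seed`. Defaults emulate the study
#' conditions at desk scale: a 9 x 9 x 10 grid parcellated into 90 regions
#' of 9 voxels, BOLD-like AR(1) voxel series of 120 samples (comfortably
#' above the 77-sample shortest-epoch floor), a two-group cohort with
#' continuous ages on [6, 30], and case-minus-control entropy gap curves
#' whose whole-brain average is a few hundredths of a nat.
#'
#' @param n_per_group Subjects per group (default 150).
#' @param age_range Age interval in years (default `c(6, 30)`).
#' @param grid_shape 3D grid extents (default `c(9, 9, 10)`).
#' @param n_regions Number of regions (default 90).
#' @param series_length Timepoints per voxel series (default 120, must be
#'   at least 77).
#' @param prop_male Proportion of male subjects (default 0.85, typical of
#'   autism cohorts).
#' @param gap_scale Multiplier on the planted case-control gap curves
#'   (0 removes the group difference).
#' @param phi_jitter_sd SD of the per-subject, per-region jitter on the AR
#'   coefficient (between-subject biological variability).
#' @param true_betas Named vector of behavioral-model coefficients used by
#'   [simulate_behavior()].
#' @param behavior_noise_sd Residual SD of the behavioral model.
#' @param seed Root seed; every stage derives a named substream from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 150L, age_range = c(6, 30),
                        grid_shape = c(9L, 9L, 10L), n_regions = 90L,
                        series_length = 120L, prop_male = 0.85,
                        gap_scale = 1, phi_jitter_sd = 0.01,
                        true_betas = c(region_35 = 150, region_36 = -250,
                                       region_41 = -20, age = -0.1, sex = -1),
                        behavior_noise_sd = 5, seed = 20240601L) {
  if (series_length < 77L) {
    abort("`series_length` must be at least 77 (the shortest-epoch floor).",
          class = "entrajectory_parameter_error")
  }
  structure(
    list(n_per_group = as.integer(n_per_group), age_range = age_range,
         grid_shape = as.integer(grid_shape), n_regions = as.integer(n_regions),
         series_length = as.integer(series_length), prop_male = prop_male,
         gap_scale = gap_scale, phi_jitter_sd = phi_jitter_sd,
         true_betas = true_betas, behavior_noise_sd = behavior_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a two-group cohort's phenotype table
#'
#' Ages are uniform over `age_range`, groups balanced, sex drawn with the
#' configured male proportion, FIQ Gaussian (mean 105, SD 20). Regenerating
#' with the same spec gives an identical table.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with `subject_id`, `group`, `age`, `sex`, `fiq`,
#'   `region_class`-independent demographics only (behavioral scores come
#'   from [simulate_behavior()]).
#' @export
simulate_cohort <- function(spec) {
  n <- 2L * spec$n_per_group
  set.seed(substream_seed(spec$seed, "cohort"))
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = factor(rep(c("case", "control"), each = spec$n_per_group),
                   levels = c("case", "control")),
    age = runif(n, spec$age_range[1], spec$age_range[2]),
    sex = factor(ifelse(runif(n) < spec$prop_male, "male", "female"),
                 levels = c("male", "female")),
    fiq = rnorm(n, 105, 20)
  )
}

#' Simulate one subject's BOLD-like volume
#'
#' Every voxel series is a standardized AR(1) process,
#' `x_t = phi * x_(t-1) + eps_t`, with `phi` set by the subject's group and
#' age through the region's template (plus a small per-subject regional
#' jitter). Higher `phi` means a smoother, more regular series and hence
#' lower sample entropy. Deterministic given (spec seed, subject id).
#'
#' @param record One row of the [simulate_cohort()] table.
#' @param spec A [cohort_spec()].
#' @param parc The toy parcellation (defaults to
#'   `make_toy_parcellation(spec$grid_shape, spec$n_regions)`).
#' @return A [bold_volume()].
#' @export
simulate_subject_bold <- function(record, spec,
                                  parc = make_toy_parcellation(spec$grid_shape,
                                                               spec$n_regions)) {
  set.seed(substream_seed(spec$seed, paste0("bold:", record$subject_id)))
  classes <- region_template_classes(spec$n_regions)
  n_t <- spec$series_length
  labels <- as.integer(parc$labels)
  n_vox <- length(labels)
  dat <- matrix(0, n_vox, n_t)
  phi_region <- vapply(seq_len(spec$n_regions), function(rid) {
    base <- template_phi(record$age, as.character(record$group),
                         classes[rid], spec$gap_scale)
    min(max(base + rnorm(1, 0, spec$phi_jitter_sd), 0), 0.95)
  }, numeric(1))
  burn <- 50L
  for (v in seq_len(n_vox)) {
    if (labels[v] == 0L) next
    phi <- phi_region[labels[v]]
    x <- as.numeric(stats::filter(rnorm(n_t + burn), phi, method = "recursive"))
    x <- x[-seq_len(burn)]
    dat[v, ] <- x / sd(x)
  }
  bold_volume(array(dat, dim = c(spec$grid_shape, n_t)),
              subject_id = record$subject_id)
}

#' Regional entropy profiles for a whole synthetic cohort
#'
#' Generates each subject's volume in turn (volumes are never all held in
#' memory) and stacks the [regional_profile()] rows.
#'
#' @param subjects Output of [simulate_cohort()].
#' @param spec The [cohort_spec()] used to generate them.
#' @param params Entropy parameters.
#' @param whole_brain Whole-brain weighting, see [regional_profile()].
#' @return A stacked `regional_profile` tibble.
#' @export
simulate_cohort_profiles <- function(subjects, spec,
                                     params = entropy_params(),
                                     whole_brain = "region") {
  parc <- make_toy_parcellation(spec$grid_shape, spec$n_regions)
  purrr::map_dfr(seq_len(nrow(subjects)), function(i) {
    vol <- simulate_subject_bold(subjects[i, ], spec, parc)
    regional_profile(vol, parc, params, whole_brain = whole_brain)
  })
}

#' Simulate behavioral scores from a known linear model
#'
#' `score = intercept + sum(beta_r * entropy_r) + beta_age * age +
#' beta_sex * sex + Gaussian noise`, with sex coded male = 0, female = 1.
#' Subjects missing any required regional entropy get a missing score.
#'
#' @param profiles Stacked regional profiles ([profiles_to_wide()] is
#'   applied internally).
#' @param subjects Cohort tibble with `age` and `sex`.
#' @param true_betas Named coefficients over `region_<id>`, `age`, `sex`.
#' @param intercept Model intercept.
#' @param noise_sd Residual SD (0 gives an exact linear system).
#' @param seed Seed for the residual draw.
#' @param score_name Name of the new score column.
#' @return `subjects` with the score column appended.
#' @export
simulate_behavior <- function(profiles, subjects,
                              true_betas = c(region_35 = 150, region_36 = -250,
                                             region_41 = -20, age = -0.1, sex = -1),
                              intercept = 0, noise_sd = 5, seed = 1L,
                              score_name = "score") {
  wide <- profiles_to_wide(profiles)
  df <- dplyr::left_join(subjects, wide, by = "subject_id")
  sex_num <- if (is.factor(df$sex)) as.numeric(df$sex == "female") else df$sex
  design <- cbind(
    sapply(setdiff(names(true_betas), c("age", "sex")),
           function(cl) df[[cl]] %||% rep(NA_real_, nrow(df))),
    age = df$age, sex = sex_num
  )
  design <- design[, names(true_betas), drop = FALSE]
  set.seed(substream_seed(seed, "behavior"))
  score <- intercept + as.numeric(design %*% true_betas) +
    rnorm(nrow(df), 0, noise_sd)
  subjects[[score_name]] <- score
  subjects
}
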