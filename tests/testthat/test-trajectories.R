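test_that("age windows enumerate starts and labels correctly", {
  w <- build_age_windows(6, 26, 5, 1)
  expect_equal(nrow(w), 21)
  expect_equal(w$label[1], "6 to 10")
  expect_equal(w$label[21], "26 to 30")
  expect_equal(w$lo, 6:26)

  expect_equal(nrow(build_age_windows(6, 6, 5, 1)), 1)

  w2 <- build_age_windows(6, 10, 5, 2)
  expect_equal(w2$lo, c(6, 8, 10))

  # count formula, checked against an explicit enumeration
  for (step in 1:3) {
    for (span in c(0, 6, 12)) {
      w3 <- build_age_windows(6, 6 + span * step, 5, step)
      expect_equal(nrow(w3), span + 1)
      expect_equal(w3$lo, seq(6, 6 + span * step, by = step))
    }
  }
  expect_error(build_age_windows(6, 5, 5, 1), class = "entrajectory_parameter_error")
  expect_error(build_age_windows(6, 26, 0, 1), class = "entrajectory_parameter_error")
})

test_that("subjects join every window whose half-open interval holds their age", {
  w <- build_age_windows(6, 26, 5, 1)
  subj <- tibble::tibble(subject_id = c("a", "b", "c"),
                         age = c(8.3, 30.78, 5.0))
  expect_message(m <- assign_to_windows(subj, w), "outside all age windows")
  # enumerate admissible windows directly from the membership rule
  expect_equal(m$window_index[m$subject_id == "a"],
               w$index[w$lo <= 8.3 & 8.3 < w$lo + 5])
  expect_equal(w$lo[m$window_index[m$subject_id == "a"]], c(6, 7, 8))
  expect_equal(w$lo[m$window_index[m$subject_id == "b"]], 26)
  expect_equal(sum(m$subject_id == "c"), 0)
  expect_equal(attr(m, "unassigned"), "c")

  # interior-aged subjects fall in exactly width/step windows, always contiguous
  set.seed(21)
  interior <- tibble::tibble(subject_id = sprintf("s%d", 1:50),
                             age = runif(50, 11, 25.999))
  mi <- assign_to_windows(interior, w)
  counts <- table(mi$subject_id)
  expect_true(all(counts == 5))
  contiguous <- tapply(mi$window_index, mi$subject_id,
                       function(ix) all(diff(sort(ix)) == 1))
  expect_true(all(contiguous))
})

test_that("normality screening reports a KS statistic without gating anything", {
  set.seed(22)
  p_normal <- replicate(100, ks_normality(rnorm(500))$p_value)
  expect_gte(mean(p_normal > 0.05), 0.90)

  stat_normal <- replicate(50, ks_normality(rnorm(500))$statistic)
  stat_unif <- replicate(50, {
    u <- runif(500)
    ks_normality((u - mean(u)) / sd(u))$statistic
  })
  expect_gt(mean(stat_unif), mean(stat_normal))

  expect_warning(out <- ks_normality(c(1, 2, 3)), "fewer than 5")
  expect_true(is.na(out$p_value))
})

test_that("GESD flags gross outliers and matches the step-by-step oracle", {
  expect_equal(gesd_outliers(1:10, max_k = 3), integer(0))
  expect_equal(gesd_outliers(c(1, 2, 3, 4, 5, 100), max_k = 2), 6L)
  expect_equal(gesd_outliers(rep(4, 10), max_k = 2), integer(0))

  set.seed(23)
  for (i in 1:200) {
    n <- sample(8:50, 1)
    x <- rnorm(n)
    if (i %% 3 == 0) x[sample(n, 2)] <- rnorm(2, 0, 8)  # plant outliers
    k <- sample(1:4, 1)
    expect_identical(gesd_outliers(x, max_k = k), gesd_oracle(x, max_k = k))
  }
})

test_that("removing GESD outliers never increases a sample's SD", {
  set.seed(24)
  for (i in 1:50) {
    x <- rnorm(30)
    if (i %% 2 == 0) x[1:2] <- c(10, -12)
    out <- gesd_outliers(x, max_k = 3)
    if (length(out) > 0) {
      expect_lte(sd(x[-out]), sd(x))
    }
  }
})

make_cell_profiles <- function(values_by_subject) {
  purrr::imap_dfr(values_by_subject, function(v, sid) {
    tibble::tibble(subject_id = sid, unit = "whole_brain",
                   region_id = NA_integer_, entropy = v,
                   n_voxels_used = 10L, n_voxels_dropped = 0L)
  })
}

test_that("group trajectories summarize screened cells with documented conventions", {
  w <- build_age_windows(6, 6, 5, 1)  # single window
  n <- 12
  subj <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep(c("case", "control"), each = n / 2),
                   levels = c("case", "control")),
    age = rep(7.5, n)
  )
  set.seed(25)
  vals <- c(rnorm(n / 2 - 1), 25, rnorm(n / 2))  # one gross case outlier
  profiles <- make_cell_profiles(stats::setNames(as.list(vals), subj$subject_id))
  m <- assign_to_windows(subj, w)
  traj <- group_trajectory(profiles, m, subj)

  case_row <- traj[traj$group == "case", ]
  ctrl_row <- traj[traj$group == "control", ]
  case_vals <- vals[1:(n / 2)]
  flagged <- gesd_oracle(case_vals, max_k = 1)
  expect_equal(case_row$n_outliers_removed, length(flagged))
  survivors <- case_vals[setdiff(seq_along(case_vals), flagged)]
  expect_equal(case_row$mean, mean(survivors))
  expect_equal(case_row$sd, sd(survivors))
  expect_equal(case_row$sem, sd(survivors) / sqrt(length(survivors)))
  expect_equal(ctrl_row$n, n / 2)

  # identical constants: equal means, zero SD, zero differential curve
  const <- make_cell_profiles(stats::setNames(as.list(rep(1.3, n)), subj$subject_id))
  traj_c <- group_trajectory(const, m, subj)
  expect_equal(unique(traj_c$mean), 1.3)
  expect_equal(unique(traj_c$sd), 0)
  dc <- differential_curves(traj_c)
  expect_equal(unique(dc$diff), 0)

  # single-subject cell: n = 1, SD 0 by convention, SEM missing
  solo <- subj[c(1, 7), ]
  traj_s <- group_trajectory(profiles[profiles$subject_id %in% solo$subject_id, ],
                             assign_to_windows(solo, w), solo)
  expect_equal(traj_s$n, c(1L, 1L))
  expect_equal(traj_s$sd, c(0, 0))
  expect_true(all(is.na(traj_s$sem)))
})

test_that("the window t test matches the pooled-variance closed form", {
  x <- c(1.1, 1.2, 1.3)
  expect_equal(window_ttest(x, x)$t, 0)
  expect_equal(window_ttest(x, x)$p_value, 1)

  set.seed(26)
  a <- rnorm(30, 0, 1)
  b <- rnorm(30, 1, 1)
  got <- window_ttest(a, b)
  sp2 <- ((30 - 1) * var(a) + (30 - 1) * var(b)) / (30 + 30 - 2)
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 30 + 1 / 30))
  p_manual <- 2 * pt(-abs(t_manual), 58)
  expect_equal(got$t, t_manual, tolerance = 1e-10)
  expect_equal(got$p_value, p_manual, tolerance = 1e-10)
  expect_equal(got$df, 58)

  expect_warning(skipped <- window_ttest(1.5, b), "skipped")
  expect_true(is.na(skipped$p_value))
})

test_that("Bonferroni correction divides the base level exactly", {
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 450), 0.05 / 450)
  expect_equal(bonferroni_alpha(0.05, 450), 1.1111e-4, tolerance = 1e-4)
  expect_error(bonferroni_alpha(0.05, 0), class = "entrajectory_parameter_error")
})

test_that("differential curves subtract control from case and respect missingness", {
  w <- build_age_windows(6, 7, 5, 1)
  subj <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:20),
    group = factor(rep(c("case", "control"), each = 10),
                   levels = c("case", "control")),
    age = c(rep(7, 5), rep(11.5, 5), rep(6.5, 10))  # no control in window 2
  )
  set.seed(27)
  deficit <- -0.02
  vals <- c(rnorm(5, 1.3 + deficit, 1e-3), rnorm(5, 1.3, 1e-3),
            rnorm(10, 1.3, 1e-3))
  profiles <- make_cell_profiles(stats::setNames(as.list(vals), subj$subject_id))
  m <- assign_to_windows(subj, w)
  traj <- group_trajectory(profiles, m, subj, screen = FALSE)
  dc <- differential_curves(traj)
  d1 <- dc$diff[dc$window_index == 1]
  expect_lt(d1, 0)                       # planted childhood deficit recovered
  expect_lt(abs(d1 - deficit), 2e-3)
  expect_true(is.na(dc$diff[dc$window_index == 2]))  # missing, not zero

  # reconstruction identity: diff + control mean = case mean where both exist
  wide <- tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(traj), "window_index", "group", "mean"),
    names_from = "group", values_from = "mean")
  joined <- dplyr::left_join(tibble::as_tibble(dc), wide, by = "window_index")
  ok <- !is.na(joined$diff)
  expect_equal(joined$diff[ok] + joined$control[ok], joined$case[ok])
})

test_that("window group tests apply overlap-based Bonferroni families", {
  w <- build_age_windows(6, 8, 5, 1)
  set.seed(28)
  n <- 30
  subj <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    group = factor(rep(c("case", "control"), length.out = n),
                   levels = c("case", "control")),
    age = runif(n, 6, 12.99)
  )
  profiles <- purrr::map_dfr(subj$subject_id, function(sid) {
    tibble::tibble(subject_id = sid,
                   unit = c("region", "region", "whole_brain"),
                   region_id = c(1L, 2L, NA),
                   entropy = rnorm(3, 1.3, 0.05),
                   n_voxels_used = 5L, n_voxels_dropped = 0L)
  })
  m <- assign_to_windows(subj, w)
  tests <- window_group_tests(profiles, m, subj, w)
  expect_equal(unique(tests$corrected_alpha[tests$unit == "whole_brain"]),
               0.05 / 5)
  expect_equal(unique(tests$corrected_alpha[tests$unit == "region"]),
               0.05 / (5 * 2))
  expect_true(all(tests$significant == (tests$p_value < tests$corrected_alpha),
                  na.rm = TRUE))
})
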