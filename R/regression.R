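#' Iterative variance-inflation-factor screening
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from regressing predictor j
#' on the remaining predictors. While any VIF exceeds `threshold`, the
#' predictor with the largest VIF is dropped (exactly collinear predictors
#' have infinite VIF and go first); the full trace of every round is
#' returned so the screening is auditable.
#'
#' @param data Data frame containing the predictor columns.
#' @param predictors Character vector of at least 2 predictor column names.
#' @param threshold VIF above which a predictor is dropped (default 10).
#' @return A list of class `vif_screen`: `survivors` (character),
#'   `trace` (tibble: round, predictor, vif, dropped).
#' @export
vif_screen <- function(data, predictors, threshold = 10) {
  if (length(predictors) < 2L) {
    abort("VIF screening needs at least 2 predictors.",
          class = "entrajectory_parameter_error")
  }
  x <- as.data.frame(data)[predictors]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) <= length(predictors) + 1L) {
    abort("Need more complete cases than predictors + 1 for VIF screening.",
          class = "entrajectory_parameter_error")
  }
  vif_one <- function(j, cols) {
    others <- setdiff(cols, j)
    fit <- lm(stats::reformulate(others, response = j), data = x)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  trace <- list()
  cols <- predictors
  round <- 0L
  repeat {
    round <- round + 1L
    if (length(cols) < 2L) break
    vifs <- vapply(cols, vif_one, numeric(1), cols = cols)
    worst <- names(vifs)[which.max(vifs)]
    drop_it <- vifs[worst] > threshold
    trace[[round]] <- tibble::tibble(
      round = round, predictor = cols, vif = unname(vifs),
      dropped = cols == worst & drop_it
    )
    if (!drop_it) break
    cols <- setdiff(cols, worst)
  }
  structure(list(survivors = cols, trace = dplyr::bind_rows(trace),
                 threshold = threshold),
            class = "vif_screen")
}

#' @export
print.vif_screen <- function(x, ...) {
  cat(sprintf("<vif_screen> threshold %g: %d survivor(s): %s\n",
              x$threshold, length(x$survivors),
              paste(x$survivors, collapse = ", ")))
  invisible(x)
}

#' Bonferroni-corrected level for a multi-predictor regression
#'
#' Dividing 0.05 among the model's predictors; with the five predictors of
#' the canonical model (three regional entropies, age, sex) this is 0.01.
#'
#' @param n_predictors Number of predictors in the model.
#' @return `0.05 / n_predictors`.
#' @export
corrected_alpha_for_model <- function(n_predictors) {
  bonferroni_alpha(0.05, n_predictors)
}

#' Multiple regression with subsample bootstrap
#'
#' Fits ordinary least squares of a behavioral score on the given
#' predictors over complete cases, then repeats the fit on `n_boot`
#' resamples each drawing `floor(subsample_frac * n)` subjects without
#' replacement (set `replace = TRUE` and `subsample_frac = 1` for the
#' classical bootstrap). Per predictor it reports the full-sample estimate
#' with its OLS p value, and the bootstrap mean, SE, percentile 95% CI and
#' sign-flip p value `2 * min(P(beta* <= 0), P(beta* >= 0))`, floored at
#' `1 / n_boot`. Under subsampling the reported `boot_se` is the spread of
#' the subsample estimates rescaled by `sqrt(m / (n - m))`, the m-out-of-n
#' correction that makes it an estimate of the full-sample standard error;
#' the percentile CI is left on the raw subsample distribution.
#'
#' @param data Data frame with the response and predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param subsample_frac Fraction of subjects drawn per resample
#'   (default 0.85).
#' @param replace Draw with replacement (classical bootstrap) instead of
#'   subsampling.
#' @param alpha Corrected significance level; defaults to
#'   [corrected_alpha_for_model()] of the predictor count.
#' @param seed Optional integer seed for reproducible resampling.
#' @return An object of class `bootstrap_regression` with [tidy()] and
#'   [glance()] methods.
#' @export
fit_bootstrap_regression <- function(data, response, predictors,
                                     n_boot = 1000L, subsample_frac = 0.85,
                                     replace = FALSE,
                                     alpha = corrected_alpha_for_model(length(predictors)),
                                     seed = NULL) {
  if (length(predictors) < 1L) {
    abort("At least one predictor is required.", class = "entrajectory_parameter_error")
  }
  if (subsample_frac <= 0 || subsample_frac > 1) {
    abort("`subsample_frac` must be in (0, 1].", class = "entrajectory_parameter_error")
  }
  if (n_boot < 1L) abort("`n_boot` must be at least 1.", class = "entrajectory_parameter_error")
  df <- as.data.frame(data)[c(response, predictors)]
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < length(predictors) + 2L) {
    abort("Too few complete cases for the requested model.",
          class = "entrajectory_parameter_error")
  }
  y <- df[[response]]
  xm <- cbind(`(Intercept)` = 1, as.matrix(df[predictors]))
  full <- lm(stats::reformulate(predictors, response = response), data = df)
  if (anyNA(coef(full))) {
    abort("Full-sample design is rank deficient; drop collinear predictors first.",
          class = "entrajectory_parameter_error")
  }
  sm <- summary(full)
  betas <- coef(full)
  coef_tab <- sm$coefficients

  m_sub <- floor(subsample_frac * n)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(betas),
                 dimnames = list(NULL, names(betas)))
  skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, m_sub, replace = replace)
    fit <- tryCatch(stats::lm.fit(xm[idx, , drop = FALSE], y[idx]),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) {
      skipped <- skipped + 1L
      next
    }
    boot[b, ] <- fit$coefficients
  }
  if (skipped > 0.1 * n_boot) {
    warn(sprintf("%d of %d bootstrap resamples skipped for singular designs.",
                 skipped, n_boot))
  }
  used <- n_boot - skipped
  # For m-out-of-n subsampling without replacement the spread of subsample
  # estimates understates the full-sample sampling error by a factor
  # sqrt((n - m) / m); rescale so boot_se estimates the full-sample SE.
  # The classical with-replacement bootstrap needs no correction.
  se_factor <- if (replace || m_sub >= n) 1 else sqrt(m_sub / (n - m_sub))
  term_stats <- purrr::map_dfr(names(betas), function(term) {
    bs <- boot[, term]
    bs <- bs[!is.na(bs)]
    p_boot <- if (length(bs) > 0L) {
      max(2 * min(mean(bs <= 0), mean(bs >= 0)), 1 / n_boot)
    } else NA_real_
    tibble::tibble(
      term = term,
      estimate = unname(betas[term]),
      std_error = unname(coef_tab[term, "Std. Error"]),
      p_ols = unname(coef_tab[term, "Pr(>|t|)"]),
      boot_mean = if (length(bs) > 0L) mean(bs) else NA_real_,
      boot_se = if (length(bs) > 1L) sd(bs) * se_factor else NA_real_,
      conf_low = if (length(bs) > 0L) unname(quantile(bs, 0.025)) else NA_real_,
      conf_high = if (length(bs) > 0L) unname(quantile(bs, 0.975)) else NA_real_,
      p_boot = p_boot
    )
  }) |>
    dplyr::mutate(significant = dplyr::if_else(
      .data$term == "(Intercept)", NA,
      .data$p_ols < alpha
    ))
  fstat <- sm$fstatistic
  model_p <- if (!is.null(fstat)) {
    unname(pf_upper(fstat[1], fstat[2], fstat[3]))
  } else NA_real_
  structure(
    list(terms = term_stats, response = response, predictors = predictors,
         r_squared = sm$r.squared, f_statistic = unname(fstat[1]),
         model_p = model_p, n_used = n, n_boot = n_boot,
         n_boot_skipped = skipped, subsample_frac = subsample_frac,
         replace = replace, alpha = alpha),
    class = "bootstrap_regression"
  )
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' @export
print.bootstrap_regression <- function(x, ...) {
  cat(sprintf("<bootstrap_regression> %s ~ %s\n", x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("n = %d complete cases, R^2 = %.3f, F = %.2f, model p = %.3g\n",
              x$n_used, x$r_squared, x$f_statistic, x$model_p))
  cat(sprintf("%d resamples of %.0f%% of subjects (%s)\n", x$n_boot,
              100 * x$subsample_frac,
              if (x$replace) "with replacement" else "without replacement"))
  print(tidy(x))
  invisible(x)
}

#' Tidy per-predictor table of a bootstrap regression
#'
#' @param x A `bootstrap_regression` object.
#' @param ... Unused.
#' @return A tibble: one row per model term with the full-sample estimate,
#'   OLS p, bootstrap mean/SE, percentile CI, sign-flip p and the
#'   corrected-level significance flag.
#' @export
tidy.bootstrap_regression <- function(x, ...) {
  x$terms
}

#' One-row model summary of a bootstrap regression
#'
#' @param x A `bootstrap_regression` object.
#' @param ... Unused.
#' @return A tibble with `r_squared`, `f_statistic`, `model_p`, `n_used`,
#'   `n_boot`, `n_boot_skipped`, `alpha`.
#' @export
glance.bootstrap_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, f_statistic = x$f_statistic,
    model_p = x$model_p, n_used = x$n_used, n_boot = x$n_boot,
    n_boot_skipped = x$n_boot_skipped, alpha = x$alpha
  )
}

#' Behavioral association analysis across scales
#'
#' Screens candidate regional-entropy predictors by iterative VIF, then
#' fits one bootstrap multiple regression per behavioral scale of the form
#' `score ~ surviving regions + age + sex`.
#'
#' @param data Tibble with one row per subject: entropy predictor columns,
#'   `age`, `sex` (factor or 0/1 numeric; male = 0 when coded from factor),
#'   and the behavioral score columns.
#' @param responses Character vector of behavioral score column names.
#' @param candidates Character vector of candidate regional entropy columns.
#' @param vif_threshold Collinearity cutoff (default 10).
#' @param ... Passed to [fit_bootstrap_regression()].
#' @return A list of class `behavior_association`: `screen` (the
#'   [vif_screen()] result) and `fits` (named list of
#'   `bootstrap_regression` objects).
#' @export
behavior_association <- function(data, responses, candidates,
                                 vif_threshold = 10, ...) {
  df <- tibble::as_tibble(data)
  if (is.factor(df$sex)) {
    df$sex <- as.numeric(df$sex == "female")  # male = 0, female = 1
  }
  screen <- vif_screen(df, candidates, threshold = vif_threshold)
  predictors <- c(screen$survivors, "age", "sex")
  fits <- purrr::map(rlang::set_names(responses), function(resp) {
    fit_bootstrap_regression(df, resp, predictors, ...)
  })
  structure(list(screen = screen, fits = fits), class = "behavior_association")
}

#' @export
tidy.behavior_association <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, resp) {
    dplyr::mutate(tidy(fit), response = resp, .before = 1L)
  })
}

#' @export
glance.behavior_association <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, resp) {
    dplyr::mutate(glance(fit), response = resp, .before = 1L)
  })
}
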