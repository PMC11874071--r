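#' Default pipeline configuration
#'
#' Returns the full configuration list the pipeline understands. Values
#' supplied in `...` (possibly nested lists) override the defaults. With
#' `input$mode = "synthetic"` the cohort is generated from
#' [cohort_spec()]; with `input$mode = "files"` the `input` block must name
#' a phenotype table, a label volume, a region table, and a directory of
#' per-subject 4D NIfTI files named `<subject_id>.nii.gz` (or `.nii`).
#'
#' @param ... Overrides merged over the defaults.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 20240601L,
    output_dir = "entrajectory_run",
    input = list(mode = "synthetic",
                 phenotypes = NULL, column_map = NULL,
                 parcellation = NULL, region_table = NULL, bold_dir = NULL),
    synthetic = list(n_per_group = 150L, age_range = c(6, 30),
                     grid_shape = c(9L, 9L, 10L), n_regions = 90L,
                     series_length = 120L, prop_male = 0.85,
                     gap_scale = 1, phi_jitter_sd = 0.01,
                     behavior_noise_sd = 5),
    entropy = list(m = 1L, r_frac = 0.15, scale = 1L, whole_brain = "region"),
    windows = list(min_lo = 6L, max_lo = 26L, width = 5L, step = 1L),
    gesd = list(alpha = 0.05, max_k = NULL),
    tests = list(base_alpha = 0.05, var_equal = TRUE),
    clustering = list(k_range = 2:6, k = NULL),
    regression = list(responses = "score",
                      candidates = c("region_35", "region_36", "region_41"),
                      vif_threshold = 10, n_boot = 1000L,
                      subsample_frac = 0.85, replace = FALSE)
  )
  overrides <- list(...)
  cfg <- modifyList(cfg, overrides)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [default_config()] keys.
#' @return A `run_config` list (defaults filled in).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "entrajectory_config_error")
  }
  do.call(default_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  if (!cfg$input$mode %in% c("synthetic", "files")) {
    abort("input$mode must be 'synthetic' or 'files'.",
          class = "entrajectory_config_error")
  }
  if (cfg$input$mode == "files") {
    for (f in c("phenotypes", "parcellation", "region_table", "bold_dir")) {
      p <- cfg$input[[f]]
      if (is.null(p) || !file.exists(p)) {
        abort(sprintf("Config input$%s missing or not found: %s", f, p %||% "<null>"),
              class = "entrajectory_config_error")
      }
    }
  }
  # constructing these validates the numeric blocks
  entropy_params(cfg$entropy$m, cfg$entropy$r_frac, cfg$entropy$scale)
  build_age_windows(cfg$windows$min_lo, cfg$windows$max_lo,
                    cfg$windows$width, cfg$windows$step)
  if (cfg$regression$subsample_frac <= 0 || cfg$regression$subsample_frac > 1) {
    abort("regression$subsample_frac must be in (0, 1].",
          class = "entrajectory_config_error")
  }
  invisible(cfg)
}

write_stage_tsv <- function(x, dir, name) {
  readr::write_tsv(tibble::as_tibble(x), file.path(dir, name), na = "NA",
                   progress = FALSE)
}

#' Run the complexity-trajectory pipeline end to end
#'
#' Stages, in order: cohort (simulate or load), entropy profiles, age-window
#' trajectories with outlier screening and group tests, differential curves,
#' clustering, behavioral association. Every table is written as TSV into
#' `output_dir`, the resolved configuration is serialized alongside for
#' provenance, and `run.log` records the seed, parameters, and everything
#' dropped on the way. A stage failure leaves a `FAILED` marker naming the
#' stage and re-raises the error.
#'
#' @param config A `run_config` from [default_config()] / [read_config()].
#' @param through Last stage to run (default the full pipeline).
#' @return The output directory path, invisibly; the key result objects are
#'   attached as the attribute `results`.
#' @export
run_pipeline <- function(config = default_config(),
                         through = c("associate", "cluster", "trajectories",
                                     "entropy", "simulate")) {
  through <- match.arg(through)
  stage_rank <- c(simulate = 1, entropy = 2, trajectories = 3,
                  cluster = 4, associate = 5)
  validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  yaml::write_yaml(unclass(config), file.path(config$output_dir, "config.yaml"))
  results <- list()
  stage <- "setup"
  run <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage %s: %s", name,
                                      conditionMessage(e))), log_path)
      file.create(file.path(config$output_dir, "FAILED"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "entrajectory_stage_error", parent = e)
    })
  }
  say("entrajectory %s | seed %d | mode %s",
      as.character(utils::packageVersion("entrajectory")),
      config$seed, config$input$mode)

  # --- cohort -------------------------------------------------------------
  run("simulate", {
    if (config$input$mode == "synthetic") {
      spec <- do.call(cohort_spec, c(config$synthetic, list(seed = config$seed)))
      subjects <- simulate_cohort(spec)
      parc <- make_toy_parcellation(spec$grid_shape, spec$n_regions)
      say("simulated cohort: %d subjects (%d per group), ages %.1f-%.1f",
          nrow(subjects), spec$n_per_group, min(subjects$age), max(subjects$age))
      results$spec <- spec
    } else {
      subjects <- read_phenotypes(config$input$phenotypes,
                                  config$input$column_map %||% abide_column_map())
      parc <- read_parcellation(config$input$parcellation,
                                config$input$region_table)
      say("loaded cohort: %d subjects, %d regions", nrow(subjects),
          nrow(parc$region_table))
    }
    results$subjects <- subjects
    results$parcellation <- parc
    write_stage_tsv(subjects, config$output_dir, "phenotypes.tsv")
  })
  if (stage_rank[through] < 2) return(finish_run(config, results, log_lines, log_path))

  # --- entropy ------------------------------------------------------------
  run("entropy", {
    params <- entropy_params(config$entropy$m, config$entropy$r_frac,
                             config$entropy$scale)
    profiles <- if (config$input$mode == "synthetic") {
      simulate_cohort_profiles(results$subjects, results$spec, params,
                               whole_brain = config$entropy$whole_brain)
    } else {
      purrr::map_dfr(seq_len(nrow(results$subjects)), function(i) {
        sid <- results$subjects$subject_id[i]
        path <- file.path(config$input$bold_dir, paste0(sid, ".nii.gz"))
        if (!file.exists(path)) path <- file.path(config$input$bold_dir,
                                                  paste0(sid, ".nii"))
        vol <- read_bold(path, subject_id = sid)
        regional_profile(vol, results$parcellation, params,
                         whole_brain = config$entropy$whole_brain)
      })
    }
    dropped <- sum(profiles$n_voxels_dropped[profiles$unit == "region"])
    say("entropy profiles: %d subjects x %d regions (m=%d, r=%.2f sd, scale=%d); %d voxel(s) with undefined entropy",
        length(unique(profiles$subject_id)),
        length(unique(profiles$region_id[profiles$unit == "region"])),
        params$m, params$r_frac, params$scale, dropped)
    results$profiles <- profiles
    write_stage_tsv(profiles_to_wide(profiles), config$output_dir, "profiles.tsv")
  })
  if (stage_rank[through] < 3) return(finish_run(config, results, log_lines, log_path))

  # --- trajectories -------------------------------------------------------
  run("trajectories", {
    windows <- build_age_windows(config$windows$min_lo, config$windows$max_lo,
                                 config$windows$width, config$windows$step)
    membership <- assign_to_windows(results$subjects, windows)
    unassigned <- attr(membership, "unassigned")
    say("windows: %d (%s ... %s); %d subject(s) unassigned%s",
        nrow(windows), windows$label[1], windows$label[nrow(windows)],
        length(unassigned),
        if (length(unassigned) > 0)
          paste0(": ", paste(head(unassigned, 10), collapse = ", ")) else "")
    traj <- group_trajectory(results$profiles, membership, results$subjects,
                             gesd_alpha = config$gesd$alpha,
                             gesd_max_k = config$gesd$max_k)
    say("trajectories: %d cells, %d outlier value(s) removed by GESD (alpha=%.2f)",
        nrow(traj), sum(traj$n_outliers_removed), config$gesd$alpha)
    tests <- window_group_tests(results$profiles, membership, results$subjects,
                                windows, base_alpha = config$tests$base_alpha,
                                gesd_alpha = config$gesd$alpha,
                                gesd_max_k = config$gesd$max_k,
                                var_equal = config$tests$var_equal)
    curves <- differential_curves(traj)
    results$windows <- windows
    results$membership <- membership
    results$trajectories <- traj
    results$tests <- tests
    results$curves <- curves
    write_stage_tsv(windows, config$output_dir, "windows.tsv")
    write_stage_tsv(traj, config$output_dir, "trajectories.tsv")
    write_stage_tsv(tests, config$output_dir, "tests.tsv")
    write_stage_tsv(curves, config$output_dir, "differential_curves.tsv")
  })
  if (stage_rank[through] < 4) return(finish_run(config, results, log_lines, log_path))

  # --- clustering ---------------------------------------------------------
  run("cluster", {
    cl <- cluster_curves(results$curves, k_range = config$clustering$k_range,
                         k = config$clustering$k)
    say("clustering: %d curves, k = %d (cluster sizes %s)%s",
        length(cl$labels), cl$k, paste(table(cl$labels), collapse = ", "),
        if (length(cl$excluded) > 0)
          sprintf("; %d curve(s) excluded for missing values", length(cl$excluded))
        else "")
    mc <- cluster_mean_curves(curves_matrix(results$curves)[names(cl$labels), ,
                                                            drop = FALSE],
                              cl$labels)
    traj_mat <- results$trajectories |>
      dplyr::filter(.data$unit == "region") |>
      dplyr::group_by(.data$window_index, .data$region_id) |>
      dplyr::summarise(mean = mean(.data$mean, na.rm = TRUE), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "region_id", values_from = "mean")
    corr <- age_group_correlations(as.matrix(traj_mat[-1]))
    results$clusters <- cl
    results$cluster_means <- mc
    results$window_correlations <- corr
    write_stage_tsv(tibble::tibble(region = names(cl$labels),
                                   cluster = unname(cl$labels)),
                    config$output_dir, "clusters.tsv")
    write_stage_tsv(cl$ch_scores, config$output_dir, "ch_scores.tsv")
    write_stage_tsv(mc$means, config$output_dir, "cluster_mean_curves.tsv")
    write_stage_tsv(mc$extremes, config$output_dir, "cluster_extremes.tsv")
    write_stage_tsv(tibble::as_tibble(as.data.frame(corr), rownames = "window"),
                    config$output_dir, "age_group_correlations.tsv")
  })
  if (stage_rank[through] < 5) return(finish_run(config, results, log_lines, log_path))

  # --- behavioral association --------------------------------------------
  run("associate", {
    wide <- profiles_to_wide(results$profiles)
    responses <- config$regression$responses
    subj <- results$subjects
    if (config$input$mode == "synthetic" && !all(responses %in% names(subj))) {
      subj <- simulate_behavior(results$profiles, subj,
                                true_betas = results$spec$true_betas,
                                noise_sd = results$spec$behavior_noise_sd,
                                seed = config$seed,
                                score_name = responses[1])
      say("simulated behavioral score '%s' from the planted linear model",
          responses[1])
    }
    df <- dplyr::left_join(subj, wide, by = "subject_id") |>
      dplyr::filter(.data$group == "case")
    assoc <- behavior_association(df, responses,
                                  candidates = config$regression$candidates,
                                  vif_threshold = config$regression$vif_threshold,
                                  n_boot = config$regression$n_boot,
                                  subsample_frac = config$regression$subsample_frac,
                                  replace = config$regression$replace,
                                  seed = substream_seed(config$seed, "bootstrap"))
    say("association: candidates %s -> survivors %s; %d response(s), %d bootstrap resamples of %.0f%% of cases",
        paste(config$regression$candidates, collapse = ", "),
        paste(assoc$screen$survivors, collapse = ", "),
        length(responses), config$regression$n_boot,
        100 * config$regression$subsample_frac)
    results$association <- assoc
    write_stage_tsv(tidy(assoc), config$output_dir, "regression.tsv")
    write_stage_tsv(glance(assoc), config$output_dir, "regression_models.tsv")
    write_stage_tsv(assoc$screen$trace, config$output_dir, "vif_trace.tsv")
  })
  finish_run(config, results, log_lines, log_path)
}

finish_run <- function(config, results, log_lines, log_path) {
  writeLines(c(log_lines, "done"), log_path)
  out <- config$output_dir
  attr(out, "results") <- results
  invisible(out)
}
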