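#' BOLD volume container
#'
#' Holds one subject's 4D resting-state BOLD array together with the mask of
#' analyzable voxels. When no mask is given, voxels whose time series has
#' zero temporal variance (e.g. out-of-brain zeros) are excluded, since
#' sample entropy is undefined for them in any informative sense.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param mask Optional 3D logical array matching the spatial shape of
#'   `data`; `NULL` selects all voxels with nonzero temporal variance.
#' @param subject_id Subject identifier.
#' @return An object of class `bold_volume`: a list with elements `data`,
#'   `mask`, `subject_id`, `n_timepoints`.
#' @export
bold_volume <- function(data, mask = NULL, subject_id = "subject") {
  if (length(dim(data)) != 4L) {
    abort("`data` must be a 4D array (x, y, z, t).", class = "entrajectory_format_error")
  }
  if (dim(data)[4] < 2L) {
    abort("BOLD volume must have at least 2 timepoints.", class = "entrajectory_length_error")
  }
  spatial <- dim(data)[1:3]
  if (is.null(mask)) {
    flat <- matrix(data, prod(spatial), dim(data)[4])
    v <- matrixStats_rowVars(flat)
    mask <- array(v > 0 & is.finite(v), dim = spatial)
  } else {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (!identical(dim(mask), as.integer(spatial))) {
      abort("Mask shape must equal the spatial shape of `data`.",
            class = "entrajectory_alignment_error")
    }
  }
  flat <- matrix(data, prod(spatial), dim(data)[4])
  bad <- which(mask)[!apply(flat[which(mask), , drop = FALSE], 1L, function(s) all(is.finite(s)))]
  if (length(bad) > 0L) {
    mask[bad] <- FALSE
    warn(sprintf("%d masked voxel(s) with non-finite values removed from the mask.", length(bad)))
  }
  structure(
    list(data = data, mask = mask, subject_id = as.character(subject_id),
         n_timepoints = dim(data)[4]),
    class = "bold_volume"
  )
}

# row variances without a matrixStats dependency
matrixStats_rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_volume> subject %s: %d x %d x %d grid, %d timepoints, %d masked voxels\n",
              x$subject_id, d[1], d[2], d[3], d[4], sum(x$mask)))
  invisible(x)
}

#' Read a 4D BOLD NIfTI file
#'
#' @param path Path to a 4D NIfTI (.nii or .nii.gz) file.
#' @param mask_path Optional path to a 3D mask NIfTI; nonzero voxels are
#'   analyzable. When absent, the nonzero-temporal-variance default applies.
#' @param subject_id Subject identifier; defaults to the file stem.
#' @return A [bold_volume()].
#' @export
read_bold <- function(path, mask_path = NULL, subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("BOLD file not found: %s", path))
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L) {
    abort(sprintf("Expected a 4D NIfTI, got %d dimensions: %s", length(dim(arr)), path),
          class = "entrajectory_format_error")
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- unclass(as.array(RNifti::readNifti(mask_path))) != 0
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  bold_volume(arr, mask = mask, subject_id = subject_id)
}

#' Write a BOLD volume to NIfTI
#'
#' @param vol A [bold_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_bold <- function(vol, path) {
  RNifti::writeNifti(RNifti::asNifti(vol$data), path)
  invisible(path)
}

#' Parcellation container
#'
#' An integer-labelled volume (0 = background) plus the region lookup table.
#' Every nonzero label present in the volume must appear in the table.
#'
#' @param labels 3D integer array of region labels.
#' @param region_table Data frame with columns `id`, `name`, `hemisphere`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, region_table) {
  region_table <- tibble::as_tibble(region_table)
  need <- c("id", "name", "hemisphere")
  if (!all(need %in% names(region_table))) {
    abort("Region table must have columns id, name, hemisphere.",
          class = "entrajectory_schema_error")
  }
  region_table$id <- as.integer(region_table$id)
  if (anyDuplicated(region_table$id)) {
    abort("Region ids must be unique.", class = "entrajectory_consistency_error")
  }
  present <- sort(unique(as.integer(labels)))
  present <- present[present != 0L]
  missing <- setdiff(present, region_table$id)
  if (length(missing) > 0L) {
    abort(sprintf("Labels present in volume but absent from region table: %s",
                  paste(missing, collapse = ", ")),
          class = "entrajectory_consistency_error")
  }
  if (length(present) == 0L) {
    warn("Parcellation volume contains no nonzero labels.")
  }
  structure(
    list(labels = array(as.integer(labels), dim = dim(labels)),
         region_table = region_table),
    class = "parcellation"
  )
}

#' @export
print.parcellation <- function(x, ...) {
  present <- setdiff(unique(as.integer(x$labels)), 0L)
  cat(sprintf("<parcellation> %d regions in table, %d populated, grid %s\n",
              nrow(x$region_table), length(present),
              paste(dim(x$labels), collapse = " x ")))
  invisible(x)
}

#' Read a label volume and its region table
#'
#' @param path Path to a 3D integer-label NIfTI.
#' @param region_table_path Delimited text (TSV/CSV) with columns
#'   `id`, `name`, `hemisphere`.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(path, region_table_path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L) {
    abort(sprintf("Expected a 3D label NIfTI, got %d dimensions.", length(dim(arr))),
          class = "entrajectory_format_error")
  }
  if (max(abs(arr - round(arr))) > 1e-6) {
    abort("Label volume is not integer-valued.", class = "entrajectory_format_error")
  }
  parcellation(round(arr), read_region_table(region_table_path))
}

#' Write a parcellation's label volume (and optionally its table)
#'
#' @param parc A [parcellation()].
#' @param path Output NIfTI path for the labels.
#' @param table_path Optional TSV path for the region table.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path, table_path = NULL) {
  RNifti::writeNifti(RNifti::asNifti(parc$labels), path)
  if (!is.null(table_path)) {
    readr::write_tsv(parc$region_table, table_path)
  }
  invisible(path)
}

#' Read a region lookup table
#'
#' @param path TSV or CSV file with header columns `id`, `name`, `hemisphere`.
#' @return A tibble with those columns, `id` integer.
#' @export
read_region_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("id", "name", "hemisphere")
  if (!all(need %in% names(tab))) {
    abort("Region table must have columns id, name, hemisphere.",
          class = "entrajectory_schema_error")
  }
  tab$id <- as.integer(tab$id)
  tibble::as_tibble(tab[need])
}

#' The packaged 90-region anatomical (AAL) lookup table
#'
#' Ninety cortical and subcortical regions of the automated anatomical
#' labeling atlas; odd ids are left-hemisphere, even ids right-hemisphere.
#'
#' @return A 90-row tibble with columns `id`, `name`, `hemisphere`.
#' @export
aal90_region_table <- function() {
  read_region_table(system.file("extdata", "aal90_regions.tsv",
                                package = "entrajectory", mustWork = TRUE))
}

#' Default phenotype column mapping (ABIDE-style names)
#'
#' @param scores Named character vector mapping tidy score names to source
#'   column names.
#' @return A list understood by [read_phenotypes()].
#' @export
abide_column_map <- function(scores = c(
                               adi_r_rrb = "ADI_RRB_TOTAL_C",
                               adi_r_onset = "ADI_R_ONSET_TOTAL_D",
                               ados_communication = "ADOS_COMM",
                               ados_stereotyped = "ADOS_STEREO_BEHAV",
                               srs_cognition = "SRS_COGNITION",
                               srs_communication = "SRS_COMMUNICATION",
                               vabs_expressive = "VINELAND_EXPRESSIVE_V_SCALED",
                               vabs_communication = "VINELAND_COMMUNICATION_STANDARD",
                               vabs_daily_living = "VINELAND_DAILYLVNG_STANDARD",
                               vabs_community = "VINELAND_COMMUNITY_V_SCALED",
                               vabs_interpersonal = "VINELAND_INTERPERSONAL_V_SCALED",
                               vabs_sum = "VINELAND_SUM_SCORES"
                             )) {
  list(
    subject_id = "SUB_ID",
    group = "DX_GROUP",
    age = "AGE_AT_SCAN",
    sex = "SEX",
    fiq = "FIQ",
    group_levels = c(case = "1", control = "2"),
    sex_levels = c(male = "1", female = "2"),
    scores = scores
  )
}

#' Read a phenotype table into one record per subject
#'
#' Mandatory fields are subject id, diagnostic group, age, and sex;
#' behavioral score cells that fail to parse become missing values rather
#' than errors, and rows with a non-numeric age are rejected with a warning.
#'
#' @param path Delimited text file with a header row.
#' @param column_map Mapping from tidy field names to source columns; see
#'   [abide_column_map()].
#' @return A tibble with columns `subject_id`, `group` (factor case/control),
#'   `age`, `sex` (factor male/female), `fiq`, and one numeric column per
#'   mapped behavioral score.
#' @export
read_phenotypes <- function(path, column_map = abide_column_map()) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  mandatory <- c("subject_id", "group", "age", "sex")
  for (field in mandatory) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(raw)) {
      abort(sprintf("Mandatory phenotype column for '%s' (%s) is missing.",
                    field, col %||% "<unmapped>"),
            class = "entrajectory_schema_error")
    }
  }
  age <- suppressWarnings(as.numeric(raw[[column_map$age]]))
  bad_age <- which(!is.finite(age) | age <= 0)
  if (length(bad_age) > 0L) {
    warn(sprintf("%d row(s) rejected for non-numeric or non-positive age.", length(bad_age)))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad_age)
  recode_levels <- function(x, levels_map) {
    out <- factor(rep(NA_character_, length(x)), levels = names(levels_map))
    for (lev in names(levels_map)) {
      out[x == levels_map[[lev]] | tolower(x) == lev] <- lev
    }
    out
  }
  out <- tibble::tibble(
    subject_id = as.character(raw[[column_map$subject_id]][keep]),
    group = recode_levels(raw[[column_map$group]][keep], column_map$group_levels),
    age = age[keep],
    sex = recode_levels(raw[[column_map$sex]][keep], column_map$sex_levels)
  )
  if (anyNA(out$group) || anyNA(out$sex)) {
    abort("Unrecognized group or sex codes in phenotype table.",
          class = "entrajectory_schema_error")
  }
  fiq_col <- column_map$fiq
  out$fiq <- if (!is.null(fiq_col) && fiq_col %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[fiq_col]][keep]))
  } else NA_real_
  for (score in names(column_map$scores)) {
    col <- column_map$scores[[score]]
    out[[score]] <- if (col %in% names(raw)) {
      suppressWarnings(as.numeric(raw[[col]][keep]))
    } else NA_real_
  }
  out
}
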