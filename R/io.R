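#' Read and write cohort covariate tables
#'
#' Cohorts travel as comma-separated text with a header row, UTF-8, "."
#' decimal: one patient per row, columns `patient_id` plus the covariate
#' names used by [score()].
#'
#' @param path CSV file path.
#' @param required Covariate columns that must be present (besides
#'   `patient_id`); defaults to the full set both built-in models need.
#' @return `read_cohort()` returns a data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path,
                        required = c("age", "baseline_alc", "bmi",
                                     "ptv_ml", "mean_heart_dose",
                                     "mean_lung_dose", "vertebrae_v20",
                                     "rt_duration", "chemo", "photons")) {
  if (!file.exists(path))
    stop(errorCondition(paste0("cohort file not found: ", path),
                        class = c("lymphoval_io_error", "error")))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("patient_id", required), names(x))
  if (length(missing_cols))
    stop(errorCondition(
      paste0("cohort file ", path, " lacks column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = c("lymphoval_schema_error", "error")))
  x
}

#' @rdname read_cohort
#' @param cohort Data frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a longitudinal ALC table
#'
#' Two dialects are accepted. Long form: columns `patient_id`, `day`,
#' `alc`, with baseline conveyed as rows at `day <= 0`. Baseline-column
#' form: the same long table restricted to on-treatment days plus a
#' `baseline_alc` column repeated per patient; it is normalised into
#' day-0 rows. Either way the returned table is long form, sorted by
#' patient and day.
#'
#' @param path CSV file path.
#' @return Data frame with columns `patient_id`, `day`, `alc`.
#' @export
read_alc <- function(path) {
  if (!file.exists(path))
    stop(errorCondition(paste0("ALC file not found: ", path),
                        class = c("lymphoval_io_error", "error")))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "alc")
  if (!all(need %in% names(x)))
    stop(errorCondition(
      paste0("ALC file ", path, " needs columns patient_id, day, alc"),
      class = c("lymphoval_schema_error", "error")))
  if ("baseline_alc" %in% names(x)) {
    base <- unique(x[, c("patient_id", "baseline_alc")])
    if (anyDuplicated(base$patient_id))
      stop(errorCondition(
        "inconsistent baseline_alc values within a patient",
        class = c("lymphoval_schema_error", "error")))
    x <- rbind(
      data.frame(patient_id = base$patient_id, day = 0L,
                 alc = base$baseline_alc, stringsAsFactors = FALSE),
      x[, need])
  }
  x <- x[order(x$patient_id, x$day), need]
  rownames(x) <- NULL
  x
}

#' Write the files of a synthetic cohort
#'
#' Emits `covariates.csv`, `alc.csv` (long dialect) and
#' `latent_probabilities.csv` (per-patient ground truth for testing)
#' into `dir`. All three round-trip through [read_cohort()] /
#' [read_alc()] / `read.csv`.
#'
#' @param cohort A `ril_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort_files <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ril_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    covariates = file.path(dir, "covariates.csv"),
    alc = file.path(dir, "alc.csv"),
    latent = file.path(dir, "latent_probabilities.csv"))
  write_cohort(cohort$covariates, paths[["covariates"]])
  utils::write.csv(cohort$alc, paths[["alc"]], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(cohort$outcomes, paths[["latent"]], row.names = FALSE,
                   quote = FALSE)
  invisible(paths)
}
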