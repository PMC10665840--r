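#' Baseline-characteristics summary table
#'
#' One row per variable: mean +/- sd for near-symmetric covariates,
#' median [IQR] for skewed ones, and count (percent) for binary or
#' categorical columns — the convention of a clinical Table 1.
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7). Percentages print as integers; full
#' precision is kept in the numeric columns.
#'
#' @param covariates Cohort covariate table.
#' @param outcomes Optional per-patient grade vector; adds incidence rows.
#' @param symmetric Columns summarised as mean +/- sd.
#' @return Data frame with columns `variable`, `summary`, and the
#'   underlying statistics (`mean`, `sd`, `median`, `q1`, `q3`,
#'   `count`, `percent`; unused entries `NA`).
#' @export
cohort_summary <- function(covariates, outcomes = NULL,
                           symmetric = c("age", "bmi")) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) == 0L)
    stop("empty cohort", call. = FALSE)
  n <- nrow(covariates)
  cols <- setdiff(names(covariates), "patient_id")
  row_tpl <- function(variable, summary, mean = NA, sd = NA, median = NA,
                      q1 = NA, q3 = NA, count = NA, percent = NA) {
    data.frame(variable = variable, summary = summary, mean = mean,
               sd = sd, median = median, q1 = q1, q3 = q3, count = count,
               percent = percent, stringsAsFactors = FALSE)
  }
  rows <- lapply(cols, function(v) {
    x <- covariates[[v]]
    if (is.numeric(x) && !all(x %in% c(0, 1))) {
      if (v %in% symmetric) {
        row_tpl(v, sprintf("%.1f ± %.1f", mean(x), stats::sd(x)),
                mean = mean(x), sd = stats::sd(x))
      } else {
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        row_tpl(v, sprintf("%.3g [%.3g–%.3g]", q[2], q[1], q[3]),
                median = q[2], q1 = q[1], q3 = q[3])
      }
    } else {
      k <- sum(x == 1 | x == TRUE)
      row_tpl(v, sprintf("%d (%.0f%%)", k, 100 * k / n),
              count = k, percent = 100 * k / n)
    }
  })
  if (!is.null(outcomes)) {
    for (lab in c("grade3plus", "grade4")) {
      k <- if (lab == "grade4") sum(outcomes == 4) else sum(outcomes >= 3)
      rows <- c(rows, list(
        row_tpl(paste0("lymphopenia_", lab),
                sprintf("%d (%.0f%%)", k, 100 * k / n),
                count = k, percent = 100 * k / n)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  out
}

report_as_list <- function(report) {
  stopifnot(inherits(report, "ril_validation"))
  list(
    model = report$model,
    outcome = report$outcome,
    n = report$n,
    n_events = report$n_events,
    c_statistic = report$c_statistic,
    ci_95 = report$ci,
    intercept_offset = report$intercept_offset,
    calibration = report$calibration
  )
}

#' Run the full simulate-score-grade-validate pipeline
#'
#' Either generates a synthetic cohort (default) or loads one from
#' `cohort_file`/`alc_file`, then validates both built-in models against
#' both severity outcomes (with intercept recalibration) and writes all
#' artifacts to `out_dir`:
#' \itemize{
#'   \item `covariates.csv`, `alc.csv`, `latent_probabilities.csv`
#'     (simulated runs only)
#'   \item `validation_report.json` — every model/outcome report
#'   \item `roc_<model>_<outcome>.csv`, `calibration_<model>_<outcome>.csv`
#'   \item `summary.csv` — baseline-characteristics table
#'   \item `manifest.json` — seed, configuration digest, input file
#'     digests, package version, timestamp
#' }
#' Every number in the report is recomputable from the emitted inputs
#' plus the manifest seed.
#'
#' @param out_dir Output directory.
#' @param n Cohort size for simulated runs.
#' @param seed Seed driving simulation and bootstrap CIs.
#' @param models Models to validate.
#' @param cohort_file,alc_file Optional external cohort instead of
#'   simulation.
#' @param recalibrate Apply the intercept update before calibration.
#' @param n_groups Calibration risk groups.
#' @param boot Bootstrap replicates for c-statistic CIs.
#' @return Invisibly, a list with the validation reports, the summary
#'   table and the manifest.
#' @export
run_pipeline <- function(out_dir, n = 100, seed = 1L,
                         models = c("christie", "mdacc"),
                         cohort_file = NULL, alc_file = NULL,
                         recalibrate = TRUE, n_groups = 3, boot = 2000) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.null(cohort_file)) {
    cohort <- simulate_cohort(sim_config(n = n, seed = seed))
    paths <- write_cohort_files(cohort, out_dir)
    cov <- cohort$covariates
    grades <- cohort$outcomes$grade
    inputs <- paths
  } else {
    cov <- read_cohort(cohort_file)
    if (is.null(alc_file))
      stop(errorCondition("an ALC file is required with --cohort",
                          class = c("lymphoval_schema_error", "error")))
    alc <- read_alc(alc_file)
    win <- data.frame(patient_id = cov$patient_id,
                      window_end = cov$rt_duration)
    gr <- grade_cohort(alc, window_end = win)
    grades <- gr$grade[match(cov$patient_id, gr$patient_id)]
    if (anyNA(grades))
      stop(errorCondition("ALC series missing for some cohort patients",
                          class = c("lymphoval_schema_error", "error")))
    inputs <- c(cohort = cohort_file, alc = alc_file)
  }

  reports <- list()
  for (m in models) {
    for (oc in c("grade3", "grade4")) {
      rep_i <- validate_model(m, cov, oc, grades = grades,
                              recalibrate = recalibrate,
                              n_groups = n_groups, boot = boot,
                              seed = seed)
      key <- paste(m, oc, sep = "_")
      reports[[key]] <- rep_i
      utils::write.csv(rep_i$roc,
                       file.path(out_dir, paste0("roc_", key, ".csv")),
                       row.names = FALSE)
      utils::write.csv(rep_i$calibration,
                       file.path(out_dir, paste0("calibration_", key,
                                                 ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(lapply(reports, report_as_list),
                       file.path(out_dir, "validation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summ <- cohort_summary(cov, outcomes = grades)
  utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    command = paste(deparse(match.call()), collapse = " "),
    seed = seed,
    n = length(grades),
    models = models,
    recalibrate = recalibrate,
    n_groups = n_groups,
    boot = boot,
    input_digests = as.list(tools::md5sum(unname(inputs))),
    package_version = as.character(utils::packageVersion("lymphoval")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(reports = reports, summary = summ, manifest = manifest))
}
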