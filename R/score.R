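#' Score patients with a logistic risk model
#'
#' Evaluates the linear predictor (log-odds) and predicted probability of a
#' `ril_model_spec` for every row of a covariate table. No imputation is
#' performed: a covariate the spec needs must be present and non-missing
#' for every patient, and any value entering a log transform must be
#' strictly positive.
#'
#' @param spec A `ril_model_spec` (or anything [resolve_model()] accepts).
#' @param covariates Data frame, one patient per row, columns named as the
#'   covariates the spec references (e.g. `age`, `baseline_alc`, `bmi`,
#'   `ptv_ml`, `mean_heart_dose`, `mean_lung_dose`, `vertebrae_v20`,
#'   `rt_duration`, `chemo`, `photons`).
#'
#' @return Data frame with columns `linear_predictor` and `probability`
#'   (plus `patient_id` when present in the input). The probability is the
#'   numerically stable inverse logit of the linear predictor.
#' @examples
#' cohort <- data.frame(age = 66, baseline_alc = 1.71, chemo = 1,
#'                      rt_duration = 32, mean_heart_dose = 4.34,
#'                      mean_lung_dose = 11.1, vertebrae_v20 = 23.5)
#' score(christie_model(), cohort)
#' @export
score <- function(spec, covariates) {
  spec <- resolve_model(spec)
  covariates <- as.data.frame(covariates)
  check_covariates(spec, covariates)

  tv <- function(covariate, transform) {
    x <- covariates[[covariate]]
    if (transform == "log") {
      if (any(x <= 0))
        stop("covariate '", covariate, "' must be > 0 (log transform), ",
             "got non-positive value(s)", call. = FALSE)
      log(x)
    } else x
  }

  lp <- rep(spec$intercept, nrow(covariates))
  for (i in seq_len(nrow(spec$terms))) {
    tr <- spec$terms[i, ]
    lp <- lp + tr$coefficient * tv(tr$covariate, tr$transform)
  }
  for (i in seq_len(NROW(spec$interactions))) {
    ir <- spec$interactions[i, ]
    lp <- lp + ir$coefficient *
      tv(ir$covariate1, ir$transform1) * tv(ir$covariate2, ir$transform2)
  }

  out <- data.frame(linear_predictor = lp, probability = stats::plogis(lp))
  if (!is.null(covariates$patient_id))
    out <- cbind(patient_id = covariates$patient_id, out)
  out
}

check_covariates <- function(spec, covariates) {
  needed <- unique(c(spec$terms$covariate,
                     spec$interactions$covariate1,
                     spec$interactions$covariate2))
  missing_cols <- setdiff(needed, names(covariates))
  if (length(missing_cols))
    stop("cohort table lacks covariate(s) required by model '", spec$name,
         "': ", paste(missing_cols, collapse = ", "), call. = FALSE)
  for (v in needed) {
    x <- covariates[[v]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop("covariate '", v, "' has missing or non-finite values; ",
           "no silent imputation is performed", call. = FALSE)
  }
  invisible(TRUE)
}

#' Equivalent dose in 2 Gy fractions (EQD2)
#'
#' Linear-quadratic conversion of a fractionation scheme to its equivalent
#' total dose delivered in 2 Gy fractions:
#' `EQD2 = n * d * (d + alpha/beta) / (2 + alpha/beta)`.
#' For example 24 fractions of 2.75 Gy at alpha/beta = 10 Gy give
#' 70.1 Gy, and 24 x 2.42 Gy give 60.1 Gy.
#'
#' @param n_fractions Number of fractions (> 0).
#' @param dose_per_fraction Dose per fraction in Gy (> 0).
#' @param alpha_beta Tissue alpha/beta ratio in Gy (> 0); 10 Gy is the
#'   conventional early-responding/tumor value.
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(n_fractions, dose_per_fraction, alpha_beta = 10) {
  if (any(n_fractions <= 0) || any(dose_per_fraction <= 0) ||
      any(alpha_beta <= 0))
    stop("all EQD2 arguments must be strictly positive", call. = FALSE)
  n_fractions * dose_per_fraction * (dose_per_fraction + alpha_beta) /
    (2 + alpha_beta)
}
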