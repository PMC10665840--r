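#' Concordance statistic (ROC AUC) with bootstrap confidence interval
#'
#' Rank-based concordance probability: the probability that a randomly
#' chosen case receives a higher predicted risk than a randomly chosen
#' non-case, ties counting one half. Computed via the Mann-Whitney
#' identity on midranks, so it is exact including ties.
#'
#' The 95% CI is a stratified bootstrap percentile interval (cases and
#' non-cases resampled separately) with `boot` replicates and a fixed
#' seed, so repeated calls are reproducible.
#'
#' @param predictions Numeric vector of predicted risks (any monotone
#'   score works; only ranks matter).
#' @param outcomes Binary vector (0/1 or logical) of observed events.
#' @param conf_level Confidence level, default 0.95.
#' @param boot Number of bootstrap replicates; 0 skips the interval.
#' @param seed Seed for the bootstrap stream.
#' @return List with `c_statistic`, `ci` (length-2 vector or `NULL`),
#'   `n_events`, `n`.
#' @export
c_statistic <- function(predictions, outcomes, conf_level = 0.95,
                        boot = 2000, seed = 1L) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(predictions) == length(outcomes),
            all(outcomes %in% c(0L, 1L)), !anyNA(predictions))
  n1 <- sum(outcomes)
  n0 <- sum(1L - outcomes)
  if (n1 == 0L || n0 == 0L)
    stop("discrimination undefined: need at least one event and one ",
         "non-event", call. = FALSE)
  auc <- .auc(predictions, outcomes, n1, n0)
  ci <- NULL
  if (boot > 0) {
    idx1 <- which(outcomes == 1L)
    idx0 <- which(outcomes == 0L)
    stats_b <- local_seed(seed, {
      vapply(seq_len(boot), function(b) {
        i1 <- idx1[sample.int(n1, n1, replace = TRUE)]
        i0 <- idx0[sample.int(n0, n0, replace = TRUE)]
        .auc(predictions[c(i1, i0)], rep(c(1L, 0L), c(n1, n0)), n1, n0)
      }, numeric(1))
    })
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(stats_b, c(a, 1 - a), type = 7))
  }
  list(c_statistic = auc, ci = ci, n_events = n1, n = n1 + n0)
}

.auc <- function(predictions, outcomes, n1, n0) {
  r <- rank(predictions)  # midranks handle ties as 1/2
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' One (FPR, TPR) point per distinct threshold, anchored at (0,0) and
#' (1,1); both coordinates are non-decreasing along the curve.
#'
#' @inheritParams c_statistic
#' @return Data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(predictions, outcomes) {
  outcomes <- as.integer(outcomes)
  n1 <- sum(outcomes); n0 <- length(outcomes) - n1
  stopifnot(n1 > 0, n0 > 0)
  ord <- order(predictions, decreasing = TRUE)
  y <- outcomes[ord]
  p <- predictions[ord]
  keep <- c(p[-length(p)] != p[-1], TRUE)  # last index of each threshold
  data.frame(
    fpr = c(0, cumsum(1 - y)[keep] / n0),
    tpr = c(0, cumsum(y)[keep] / n1),
    threshold = c(Inf, p[keep])
  )
}

#' Calibration in equally sized risk groups
#'
#' Patients are ranked by predicted risk and split into `n_groups`
#' contiguous groups of near-equal size (risk tertiles by default, the
#' conventional calibration-plot grouping for a 100-patient cohort).
#' When the cohort size is not divisible, the remainder patients go to
#' the lowest-risk groups. Ties in predicted risk keep stable input
#' order; a fully constant prediction vector is flagged `degenerate`.
#'
#' @inheritParams c_statistic
#' @param n_groups Number of risk groups (>= 2), default 3.
#' @return Data frame with one row per group: `group`, `n`,
#'   `mean_predicted`, `observed`, plus attribute `degenerate`.
#' @export
calibration_groups <- function(predictions, outcomes, n_groups = 3) {
  outcomes <- as.integer(outcomes)
  n <- length(predictions)
  stopifnot(length(outcomes) == n)
  if (n_groups < 2) stop("n_groups must be >= 2", call. = FALSE)
  if (n < n_groups)
    stop("cohort smaller than the number of risk groups", call. = FALSE)
  ord <- order(predictions)  # stable for ties
  sizes <- rep(n %/% n_groups, n_groups)
  rem <- n %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  grp <- rep(seq_len(n_groups), sizes)
  out <- data.frame(
    group = seq_len(n_groups),
    n = sizes,
    mean_predicted = as.numeric(
      tapply(predictions[ord], grp, mean)),
    observed = as.numeric(tapply(outcomes[ord], grp, mean))
  )
  attr(out, "degenerate") <- length(unique(predictions)) == 1L
  out
}

#' Intercept update (recalibration-in-the-large)
#'
#' Finds the log-odds shift `delta` such that the sum of shifted
#' predicted probabilities equals the observed number of events:
#' `sum(plogis(lp + delta)) = n_events`. The event sum is strictly
#' increasing in `delta`, so the solution is unique; it is found by
#' bisection on [-50, 50] followed by a Newton polish, to within 1e-8 on
#' the event sum. Shifting the intercept preserves patient ranking, so
#' discrimination is unchanged.
#'
#' @param linear_predictors Log-odds from the uncalibrated model.
#' @param n_events Observed number of events (may be non-integer when
#'   targeting an expected incidence); must lie strictly between 0 and
#'   the cohort size.
#' @return The shift `delta` (log-odds).
#' @export
update_intercept <- function(linear_predictors, n_events) {
  n <- length(linear_predictors)
  stopifnot(n > 0, all(is.finite(linear_predictors)))
  if (n_events <= 0 || n_events >= n)
    stop("no finite intercept update exists for n_events = ", n_events,
         " with ", n, " patients", call. = FALSE)
  f <- function(d) sum(stats::plogis(linear_predictors + d)) - n_events
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("event sum not bracketed on [-50, 50]; linear predictors are ",
         "extreme", call. = FALSE)
  for (it in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-8) break
    if (fm < 0) lo <- mid else hi <- mid
  }
  # one Newton polish; derivative sum(p(1-p)) > 0
  p <- stats::plogis(linear_predictors + mid)
  deriv <- sum(p * (1 - p))
  if (deriv > 0) {
    cand <- mid - f(mid) / deriv
    if (abs(f(cand)) < abs(f(mid))) mid <- cand
  }
  mid
}

#' Recalibrate a model's intercept to an observed incidence
#'
#' Returns the spec with `intercept + delta`, where `delta` is the
#' [update_intercept()] solution for the supplied cohort linear
#' predictors and observed event count. Coefficients are never touched.
#' This also covers cross-grade transfer, e.g. pointing the Christie
#' grade >=3 model at an observed grade 4 incidence.
#'
#' @param spec A `ril_model_spec`.
#' @param linear_predictors Cohort log-odds under `spec`.
#' @param n_events Observed events for the target outcome.
#' @return List with `spec` (recalibrated `ril_model_spec`) and `delta`.
#' @export
recalibrate_intercept <- function(spec, linear_predictors, n_events) {
  spec <- resolve_model(spec)
  delta <- update_intercept(linear_predictors, n_events)
  new <- spec
  new$intercept <- spec$intercept + delta
  new$name <- paste0(spec$name, "_recalibrated")
  list(spec = new, delta = delta)
}

#' Univariable logistic regression screen
#'
#' Maximum-likelihood fit of `outcome ~ x` (IRLS via [stats::glm()]),
#' reporting the odds ratio per unit of `x` with Wald 95% confidence
#' interval and two-sided p-value — the conventional crude-association
#' screen reported alongside external validation. Complete or
#' quasi-complete separation is flagged rather than reported as a
#' spuriously huge estimate.
#'
#' @param x Numeric or binary predictor.
#' @param outcomes Binary outcome vector.
#' @param variable Label for the output row.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row data frame: `variable`, `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p_value`, `separation`.
#' @export
univariable_logistic <- function(x, outcomes, variable = "x",
                                 conf_level = 0.95) {
  outcomes <- as.integer(outcomes)
  stopifnot(length(x) == length(outcomes),
            all(outcomes %in% 0:1))
  if (sum(outcomes) == 0L || sum(outcomes) == length(outcomes))
    stop("need at least one event and one non-event", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("predictor is constant", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(outcomes ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  co <- summary(fit)$coefficients
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  eps <- 1e-8
  fitted <- fit$fitted.values
  separated <- any(fitted > 1 - eps & outcomes == 1L) &&
    any(fitted < eps & outcomes == 0L) || se > 100 || !fit$converged
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(
    variable = variable,
    odds_ratio = exp(beta),
    ci_lower = exp(beta - z * se),
    ci_upper = exp(beta + z * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    separation = separated,
    stringsAsFactors = FALSE
  )
}

#' External validation of a risk model on a cohort
#'
#' Scores the cohort with the model, grades outcomes from ALC nadirs (or
#' takes pre-computed binary outcomes), and assembles the external
#' performance report: c-statistic with bootstrap CI, ROC points,
#' calibration in risk groups, and — optionally — the intercept update
#' that matches the sum of predicted probabilities to the observed event
#' count. Deterministic given inputs and `seed`.
#'
#' @param spec Model (`ril_model_spec`, `"christie"`, `"mdacc"`, or a
#'   spec-file path).
#' @param covariates Cohort covariate table (see [score()]).
#' @param outcome Either the string `"grade3"`/`"grade4"` (outcomes are
#'   then graded from `alc`/`grades`) or a binary vector.
#' @param alc Long-format ALC table (used when `outcome` is a grade
#'   label and `grades` is missing).
#' @param grades Optional pre-computed per-patient grade vector aligned
#'   with `covariates`.
#' @param recalibrate If `TRUE`, report calibration after the intercept
#'   update; the offset applied is recorded in `intercept_offset`.
#' @param n_groups Calibration groups, default 3 (tertiles).
#' @param window_end Nadir window passed to [grade_cohort()].
#' @param boot,seed Bootstrap settings for the c-statistic CI.
#' @return Object of class `ril_validation`: list with `model`,
#'   `outcome`, `n`, `n_events`, `c_statistic`, `ci`, `roc`,
#'   `calibration`, `intercept_offset`, `predictions`.
#' @export
validate_model <- function(spec, covariates, outcome, alc = NULL,
                           grades = NULL, recalibrate = FALSE,
                           n_groups = 3, window_end = 32,
                           boot = 2000, seed = 1L) {
  spec <- resolve_model(spec)
  covariates <- as.data.frame(covariates)
  if (is.character(outcome) && length(outcome) == 1L) {
    lab <- match.arg(outcome, c("grade3", "grade4"))
    if (is.null(grades)) {
      if (is.null(alc))
        stop("supply `alc` or `grades` to derive the ", lab, " outcome",
             call. = FALSE)
      gr <- grade_cohort(alc, window_end = window_end)
      gr <- gr[match(covariates$patient_id, gr$patient_id), ]
      if (anyNA(gr$grade))
        stop("ALC table lacks series for some cohort patients",
             call. = FALSE)
      grades <- gr$grade
    }
    y <- if (lab == "grade4") as.integer(grades == 4L)
         else as.integer(grades >= 3L)
  } else {
    lab <- "custom"
    y <- as.integer(outcome)
  }
  stopifnot(length(y) == nrow(covariates))

  sc <- score(spec, covariates)
  delta <- 0
  if (isTRUE(recalibrate)) {
    delta <- update_intercept(sc$linear_predictor, sum(y))
    sc$linear_predictor <- sc$linear_predictor + delta
    sc$probability <- stats::plogis(sc$linear_predictor)
  }
  cs <- c_statistic(sc$probability, y, boot = boot, seed = seed)
  structure(list(
    model = spec$name,
    outcome = lab,
    n = length(y),
    n_events = sum(y),
    c_statistic = cs$c_statistic,
    ci = cs$ci,
    roc = roc_points(sc$probability, y),
    calibration = calibration_groups(sc$probability, y, n_groups),
    intercept_offset = delta,
    predictions = data.frame(
      patient_id = if (is.null(covariates$patient_id))
        seq_along(y) else covariates$patient_id,
      linear_predictor = sc$linear_predictor,
      probability = sc$probability,
      outcome = y)
  ), class = "ril_validation")
}

#' @export
print.ril_validation <- function(x, ...) {
  cat(sprintf("External validation: %s model, %s outcome\n",
              x$model, x$outcome))
  cat(sprintf("  n = %d, events = %d (%.0f%%)\n",
              x$n, x$n_events, 100 * x$n_events / x$n))
  ci <- if (is.null(x$ci)) "" else
    sprintf(" (95%% CI: %.2f-%.2f)", x$ci[1], x$ci[2])
  cat(sprintf("  c-statistic = %.2f%s\n", x$c_statistic, ci))
  if (x$intercept_offset != 0)
    cat(sprintf("  intercept updated by %+.3f log-odds\n",
                x$intercept_offset))
  cat("  calibration (risk groups):\n")
  print(x$calibration, row.names = FALSE)
  invisible(x)
}
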