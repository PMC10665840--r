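test_that("c-statistic matches hand-worked examples and tie convention", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0),
                           boot = 0)$c_statistic, 1)
  expect_equal(c_statistic(c(0.5, 0.5), c(1, 0), boot = 0)$c_statistic, 0.5)
  expect_equal(c_statistic(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0),
                           boot = 0)$c_statistic, 0.75)
  expect_error(c_statistic(c(0.2, 0.8), c(1, 1), boot = 0), "undefined")
})

test_that("c-statistic equals exhaustive pairwise concordance with ties", {
  set.seed(21)
  for (trial in 1:60) {
    n <- sample(4:30, 1)
    pred <- sample(round(runif(n, 0, 1), 1))  # coarse grid forces ties
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(c_statistic(pred, y, boot = 0)$c_statistic,
                 brute_force_auc(pred, y), tolerance = 1e-12)
    # complement symmetry
    expect_equal(c_statistic(pred, y, boot = 0)$c_statistic +
                   c_statistic(pred, 1 - y, boot = 0)$c_statistic, 1,
                 tolerance = 1e-12)
  }
})

test_that("c-statistic agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  pred <- runif(150)
  y <- rbinom(150, 1, plogis(3 * pred - 1.5))
  expect_equal(c_statistic(pred, y, boot = 0)$c_statistic,
               as.numeric(pROC::auc(pROC::roc(y, pred, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("bootstrap CI is reproducible and brackets the estimate", {
  set.seed(14)
  pred <- runif(120)
  y <- rbinom(120, 1, plogis(2 * pred - 1))
  a <- c_statistic(pred, y, boot = 500, seed = 3)
  b <- c_statistic(pred, y, boot = 500, seed = 3)
  expect_identical(a, b)
  expect_lte(a$ci[1], a$c_statistic)
  expect_gte(a$ci[2], a$c_statistic)
})

test_that("ROC points run from (0,0) to (1,1) non-decreasingly", {
  set.seed(9)
  pred <- round(runif(80), 2)
  y <- rbinom(80, 1, pred)
  r <- roc_points(pred, y)
  expect_equal(unlist(r[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r[nrow(r), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("risk tertiles split by rank with remainder to the lowest groups", {
  g <- calibration_groups(c(0.1, 0.2, 0.4, 0.5, 0.7, 0.8),
                          c(0, 0, 0, 1, 1, 1), n_groups = 3)
  expect_equal(g$n, c(2L, 2L, 2L))
  expect_equal(g$mean_predicted, c(0.15, 0.45, 0.75))
  expect_equal(g$observed, c(0, 0.5, 1))
  expect_false(attr(g, "degenerate"))

  # 100 patients in 3 groups: remainder goes low
  g100 <- calibration_groups(runif(100), rbinom(100, 1, 0.5), 3)
  expect_equal(g100$n, c(34L, 33L, 33L))
  expect_equal(sum(g100$n), 100L)

  const <- calibration_groups(rep(0.3, 6), c(0, 1, 0, 1, 0, 1), 3)
  expect_true(attr(const, "degenerate"))

  singleton <- calibration_groups(c(0.2, 0.5, 0.9), c(0, 1, 1), 3)
  expect_true(all(singleton$observed %in% c(0, 1)))

  expect_error(calibration_groups(runif(10), rbinom(10, 1, 0.5), 1),
               ">= 2")
  expect_error(calibration_groups(runif(2), c(0, 1), 3), "smaller")
})

test_that("intercept update solves the event-sum equation exactly", {
  expect_equal(update_intercept(c(0, 0), 1), 0, tolerance = 1e-8)
  expect_equal(update_intercept(c(-1, 0, 1), 2), 0.8029344,
               tolerance = 1e-6)
  expect_error(update_intercept(c(-1, 0, 1), 3), "no finite")
  expect_error(update_intercept(c(-1, 0, 1), 0), "no finite")

  set.seed(33)
  for (trial in 1:25) {
    n <- sample(10:200, 1)
    lp <- rnorm(n, sd = 2)
    ev <- sample(seq_len(n - 1), 1)
    d <- update_intercept(lp, ev)
    expect_lt(abs(sum(plogis(lp + d)) - ev), 1e-6)
    expect_equal(d, bisect_delta(lp, ev), tolerance = 1e-6)
    # correct sign relative to the uncorrected event sum
    expect_equal(sign(d), sign(ev - sum(plogis(lp))))
  }
})

test_that("recalibration shifts the intercept only and preserves ranking", {
  cov <- random_covariates(80, seed = 2)
  set.seed(2)
  y <- rbinom(80, 1, 0.3)
  spec <- mdacc_model()
  lp <- score(spec, cov)$linear_predictor
  rc <- recalibrate_intercept(spec, lp, sum(y))
  expect_equal(rc$spec$terms, spec$terms)
  expect_equal(rc$spec$intercept, spec$intercept + rc$delta)
  p_new <- score(rc$spec, cov)$probability
  expect_lt(abs(sum(p_new) - sum(y)), 1e-6)
  # rank invariance: bit-identical c-statistic before and after
  expect_identical(c_statistic(plogis(lp), y, boot = 0)$c_statistic,
                   c_statistic(p_new, y, boot = 0)$c_statistic)
  # group membership unchanged, group means shifted
  g0 <- calibration_groups(plogis(lp), y)
  g1 <- calibration_groups(p_new, y)
  expect_equal(g0$observed, g1$observed)
  expect_false(isTRUE(all.equal(g0$mean_predicted, g1$mean_predicted)))
})

test_that("univariable logistic matches the closed-form 2x2 odds ratio", {
  # 10 events / 10 non-events exposed; 5 events / 15 non-events unexposed
  x <- rep(c(1, 0), c(20, 20))
  y <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15))
  r <- univariable_logistic(x, y, variable = "exposure")
  expect_equal(r$odds_ratio, 3.0, tolerance = 1e-6)
  expect_false(r$separation)
  se_closed <- sqrt(1 / 10 + 1 / 10 + 1 / 5 + 1 / 15)
  expect_equal(log(r$ci_upper / r$odds_ratio) / qnorm(0.975), se_closed,
               tolerance = 1e-6)
  expect_true(r$ci_lower < r$odds_ratio & r$odds_ratio < r$ci_upper)

  # null case: balanced design, x independent of outcome
  x0 <- rep(c(0, 1), 50)
  y0 <- rep(c(0, 1, 1, 0), 25)
  expect_equal(univariable_logistic(x0, y0)$odds_ratio, 1,
               tolerance = 1e-6)

  # complete separation is flagged
  sep <- univariable_logistic(c(1, 2, 3, 10, 11, 12),
                              c(0, 0, 0, 1, 1, 1))
  expect_true(sep$separation)

  expect_error(univariable_logistic(rep(1, 10), rbinom(10, 1, 0.5)),
               "constant")
})

test_that("validate_model assembles a complete, deterministic report", {
  cfg <- sim_config(n = 150, seed = 6)
  cohort <- simulate_cohort(cfg)
  rep1 <- validate_model("mdacc", cohort$covariates, "grade4",
                         grades = cohort$outcomes$grade,
                         recalibrate = TRUE, boot = 300, seed = 5)
  expect_s3_class(rep1, "ril_validation")
  expect_equal(rep1$n, 150)
  expect_equal(sum(rep1$calibration$n), 150)
  expect_true(rep1$c_statistic > 0 && rep1$c_statistic < 1)
  expect_length(rep1$ci, 2)
  # recalibrated: sum of predictions equals events
  expect_lt(abs(sum(rep1$predictions$probability) - rep1$n_events), 1e-6)
  # determinism
  rep2 <- validate_model("mdacc", cohort$covariates, "grade4",
                         grades = cohort$outcomes$grade,
                         recalibrate = TRUE, boot = 300, seed = 5)
  expect_identical(rep1, rep2)
  # outcomes derivable from the ALC table instead of grades
  rep3 <- validate_model("mdacc", cohort$covariates, "grade4",
                         alc = cohort$alc, window_end = 33,
                         boot = 0)
  expect_equal(rep3$n_events, sum(cohort$outcomes$grade4))
})
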