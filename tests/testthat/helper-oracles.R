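# Independent oracles used across the suite. These deliberately restate
# the published formulas as plain scalar arithmetic so that agreement
# with score() checks the ModelSpec machinery, not itself.

oracle_christie_lp <- function(cv) {
  -4.654 + 0.019 * cv$age - 0.544 * cv$baseline_alc + 0.435 * cv$chemo +
    0.090 * cv$rt_duration + 0.028 * cv$mean_heart_dose +
    0.046 * cv$mean_lung_dose + 0.014 * cv$vertebrae_v20
}

oracle_mdacc_lp <- function(cv) {
  -22.845 + 0.021 * cv$age - 1.019 * cv$baseline_alc + 0.516 * cv$bmi +
    3.579 * log(cv$ptv_ml) - 0.086 * cv$bmi * log(cv$ptv_ml) +
    0.949 * cv$photons
}

# exhaustive pairwise concordance: P(case > control) + 0.5 P(tie)
brute_force_auc <- function(pred, y) {
  cases <- pred[y == 1]
  controls <- pred[y == 0]
  total <- 0
  for (a in cases) for (b in controls)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cases) * length(controls))
}

# monotone-bisection oracle for the intercept update
bisect_delta <- function(lp, n_events, tol = 1e-12) {
  f <- function(d) sum(plogis(lp + d)) - n_events
  lo <- -60; hi <- 60
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

random_covariates <- function(n, seed) {
  set.seed(seed)
  data.frame(
    age = runif(n, 30, 90),
    baseline_alc = runif(n, 0.3, 4),
    bmi = runif(n, 16, 45),
    ptv_ml = runif(n, 50, 1500),
    mean_heart_dose = runif(n, 0.5, 30),
    mean_lung_dose = runif(n, 2, 25),
    vertebrae_v20 = runif(n, 0, 100),
    rt_duration = sample(28:40, n, replace = TRUE),
    chemo = sample(0:1, n, replace = TRUE),
    photons = sample(0:1, n, replace = TRUE)
  )
}
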