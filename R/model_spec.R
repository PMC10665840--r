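#' Logistic risk-model specifications
#'
#' A `ril_model_spec` is a frozen logistic scoring rule: an intercept,
#' main-effect terms (each a covariate, a transform, and a coefficient),
#' and optional two-way interaction terms. Coefficients are never refitted
#' by this package; the only permitted update is an intercept shift
#' (see [update_intercept()]).
#'
#' @param name Model label.
#' @param intercept Intercept on the log-odds scale.
#' @param terms Data frame with columns `covariate`, `transform`
#'   (`"identity"` or `"log"`, natural logarithm), `coefficient`.
#' @param interactions Data frame with columns `covariate1`, `transform1`,
#'   `covariate2`, `transform2`, `coefficient`, or `NULL` for none.
#'
#' @return An object of class `ril_model_spec`.
#' @seealso [christie_model()], [mdacc_model()], [score()]
#' @export
model_spec <- function(name, intercept, terms, interactions = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(
    is.character(name), length(name) == 1L,
    is.numeric(intercept), length(intercept) == 1L, is.finite(intercept),
    all(c("covariate", "transform", "coefficient") %in% names(terms)),
    all(terms$transform %in% c("identity", "log")),
    all(is.finite(terms$coefficient)),
    !anyDuplicated(terms$covariate)
  )
  if (!is.null(interactions)) {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    stopifnot(
      all(c("covariate1", "transform1", "covariate2", "transform2",
            "coefficient") %in% names(interactions)),
      all(c(interactions$transform1, interactions$transform2) %in%
            c("identity", "log")),
      all(is.finite(interactions$coefficient))
    )
  }
  structure(
    list(name = name, intercept = intercept,
         terms = terms[, c("covariate", "transform", "coefficient")],
         interactions = if (is.null(interactions)) NULL else
           interactions[, c("covariate1", "transform1", "covariate2",
                            "transform2", "coefficient")]),
    class = "ril_model_spec"
  )
}

#' @export
print.ril_model_spec <- function(x, ...) {
  cat("Logistic risk model:", x$name, "\n")
  cat("  intercept:", format(x$intercept), "\n")
  for (i in seq_len(nrow(x$terms))) {
    tr <- x$terms[i, ]
    lab <- if (tr$transform == "log") sprintf("log(%s)", tr$covariate)
           else tr$covariate
    cat(sprintf("  %+.4g * %s\n", tr$coefficient, lab))
  }
  for (i in seq_len(NROW(x$interactions))) {
    ir <- x$interactions[i, ]
    l1 <- if (ir$transform1 == "log") sprintf("log(%s)", ir$covariate1)
          else ir$covariate1
    l2 <- if (ir$transform2 == "log") sprintf("log(%s)", ir$covariate2)
          else ir$covariate2
    cat(sprintf("  %+.4g * %s * %s\n", ir$coefficient, l1, l2))
  }
  invisible(x)
}

#' The Christie grade >=3 lymphopenia model
#'
#' Dosimetry-based logistic model predicting grade >=3 lymphopenia during
#' concurrent chemoradiotherapy, developed at The Christie in lung cancer.
#' Log-odds = -4.654 + 0.019*age - 0.544*baseline_alc + 0.435*chemo +
#' 0.090*rt_duration + 0.028*mean_heart_dose + 0.046*mean_lung_dose +
#' 0.014*vertebrae_v20. Doses in Gy, ALC in K/uL, duration in days,
#' vertebrae V20Gy in percent.
#'
#' @return A `ril_model_spec`.
#' @export
christie_model <- function() {
  model_spec(
    name = "christie",
    intercept = -4.654,
    terms = data.frame(
      covariate = c("age", "baseline_alc", "chemo", "rt_duration",
                    "mean_heart_dose", "mean_lung_dose", "vertebrae_v20"),
      transform = "identity",
      coefficient = c(0.019, -0.544, 0.435, 0.090, 0.028, 0.046, 0.014),
      stringsAsFactors = FALSE
    )
  )
}

#' The MDACC grade 4 lymphopenia model
#'
#' PTV-based logistic model predicting grade 4 lymphopenia, developed at
#' MD Anderson Cancer Center in esophageal cancer. Log-odds = -22.845 +
#' 0.021*age - 1.019*baseline_alc + 0.516*bmi + 3.579*log(ptv_ml) -
#' 0.086*bmi*log(ptv_ml) + 0.949*photons, with the natural logarithm of
#' the planning target volume in millilitres.
#'
#' Because of the negative BMI-by-log(PTV) interaction, the marginal
#' log(PTV) slope is 3.579 - 0.086*BMI: risk increases with PTV up to
#' BMI = 3.579/0.086 (about 41.6 kg/m^2) and the direction flips above it.
#'
#' @return A `ril_model_spec`.
#' @export
mdacc_model <- function() {
  model_spec(
    name = "mdacc",
    intercept = -22.845,
    terms = data.frame(
      covariate = c("age", "baseline_alc", "bmi", "ptv_ml", "photons"),
      transform = c("identity", "identity", "identity", "log", "identity"),
      coefficient = c(0.021, -1.019, 0.516, 3.579, 0.949),
      stringsAsFactors = FALSE
    ),
    interactions = data.frame(
      covariate1 = "bmi", transform1 = "identity",
      covariate2 = "ptv_ml", transform2 = "log",
      coefficient = -0.086,
      stringsAsFactors = FALSE
    )
  )
}

#' Look up a built-in model by name or read a spec file
#'
#' @param model A `ril_model_spec`, one of `"christie"`/`"mdacc"`, or a
#'   path to a YAML spec file.
#' @return A `ril_model_spec`.
#' @export
resolve_model <- function(model) {
  if (inherits(model, "ril_model_spec")) return(model)
  stopifnot(is.character(model), length(model) == 1L)
  switch(model,
    christie = christie_model(),
    mdacc = mdacc_model(),
    {
      if (!file.exists(model))
        stop("unknown model '", model,
             "': not a built-in name and no such file", call. = FALSE)
      read_model_spec(model)
    }
  )
}

#' Read / write model specifications
#'
#' Specs serialise to YAML with keys `name`, `intercept`, `terms` (list of
#' covariate/transform/coefficient) and `interactions`. A spec round-trips
#' losslessly: `read_model_spec(write_model_spec(spec, f))` is identical
#' to `spec`.
#'
#' @param spec A `ril_model_spec`.
#' @param path File path.
#' @return `write_model_spec()` returns `path` invisibly;
#'   `read_model_spec()` returns a `ril_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "ril_model_spec"))
  obj <- list(
    name = spec$name,
    intercept = spec$intercept,
    terms = lapply(seq_len(nrow(spec$terms)), function(i)
      as.list(spec$terms[i, ])),
    interactions = if (is.null(spec$interactions)) list() else
      lapply(seq_len(nrow(spec$interactions)), function(i)
        as.list(spec$interactions[i, ]))
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  terms <- do.call(rbind, lapply(obj$terms, as.data.frame,
                                 stringsAsFactors = FALSE))
  interactions <- if (length(obj$interactions))
    do.call(rbind, lapply(obj$interactions, as.data.frame,
                          stringsAsFactors = FALSE)) else NULL
  model_spec(obj$name, obj$intercept, terms, interactions)
}
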