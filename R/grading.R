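#' CTCAE v5 lymphopenia grade from an ALC nadir
#'
#' Grade 4 when the nadir absolute lymphocyte count is below 0.2 K/uL,
#' grade 3 when it is at least 0.2 but below 0.5 K/uL, otherwise grade
#' <= 2 (coded 0; the paper-relevant grades 1-2 are not subdivided).
#' Both thresholds are strict: a nadir of exactly 0.5 is not grade 3.
#'
#' @param nadir_alc Nadir ALC in K/uL (vectorised, >= 0).
#' @return Integer vector of grades in \{0, 3, 4\}.
#' @export
grade_from_nadir <- function(nadir_alc) {
  if (anyNA(nadir_alc) || any(nadir_alc < 0))
    stop("nadir ALC must be non-negative and non-missing", call. = FALSE)
  ifelse(nadir_alc < 0.2, 4L, ifelse(nadir_alc < 0.5, 3L, 0L))
}

#' ALC nadir during treatment
#'
#' The nadir is the lowest ALC measured strictly after treatment start
#' (day 0) and no later than `window_end`; baseline measurements at
#' day <= 0 never count. Ties in value resolve to the earliest day.
#' Measurements after `window_end` are dropped with a warning.
#'
#' @param series Data frame with columns `day` (integer days since first
#'   fraction; day <= 0 is baseline) and `alc` (K/uL), or a list of such
#'   frames.
#' @param window_end Last day of the nadir window (> 0), typically the
#'   last fraction day.
#' @return A one-row data frame with `nadir_alc`, `nadir_day`, `grade`.
#' @export
alc_nadir <- function(series, window_end = 32) {
  series <- as.data.frame(series)
  stopifnot(all(c("day", "alc") %in% names(series)),
            window_end > 0)
  if (anyNA(series$alc) || any(series$alc < 0) || any(!is.finite(series$alc)))
    stop("ALC values must be finite and non-negative", call. = FALSE)
  late <- series$day > window_end
  if (any(late)) {
    warning(sum(late), " measurement(s) after day ", window_end,
            " ignored", call. = FALSE)
  }
  on_rx <- series[series$day > 0 & !late, , drop = FALSE]
  if (nrow(on_rx) == 0L)
    stop("no on-treatment ALC measurements in (0, ", window_end, "]",
         call. = FALSE)
  on_rx <- on_rx[order(on_rx$day), , drop = FALSE]
  i <- which.min(on_rx$alc)  # first minimum: earliest day wins ties
  data.frame(nadir_alc = on_rx$alc[i], nadir_day = on_rx$day[i],
             grade = grade_from_nadir(on_rx$alc[i]))
}

#' Per-patient nadirs and grades for a longitudinal ALC table
#'
#' @param alc Long-format data frame with columns `patient_id`, `day`,
#'   `alc` (the dialect written by [simulate_cohort()] and accepted by
#'   [read_alc()]).
#' @param window_end Scalar window, or a named vector/data frame
#'   (`patient_id`, `window_end`) giving per-patient windows such as each
#'   patient's last fraction day.
#' @return Data frame with one row per patient: `patient_id`,
#'   `nadir_alc`, `nadir_day`, `grade`.
#' @export
grade_cohort <- function(alc, window_end = 32) {
  alc <- as.data.frame(alc)
  stopifnot(all(c("patient_id", "day", "alc") %in% names(alc)))
  win <- window_end
  if (is.data.frame(win)) {
    stopifnot(all(c("patient_id", "window_end") %in% names(win)))
    win <- stats::setNames(win$window_end, win$patient_id)
  }
  ids <- unique(alc$patient_id)
  res <- lapply(ids, function(id) {
    w <- if (length(win) == 1L && is.null(names(win))) win
         else unname(win[[as.character(id)]])
    cbind(patient_id = id,
          alc_nadir(alc[alc$patient_id == id, ], window_end = w))
  })
  do.call(rbind, res)
}

#' Cohort incidence of severe lymphopenia
#'
#' @param grades Integer vector of CTCAE grades (from
#'   [grade_from_nadir()] or the `grade` column of [grade_cohort()]).
#' @return Named numeric vector: proportion with grade >= 3 and
#'   proportion with grade 4.
#' @export
cohort_incidence <- function(grades) {
  if (length(grades) == 0L)
    stop("empty cohort: no grades supplied", call. = FALSE)
  c(grade3plus = mean(grades >= 3), grade4 = mean(grades == 4))
}
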