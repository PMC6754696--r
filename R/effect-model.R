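#' Effect measures: remission and QALYs
#'
#' The cost-effectiveness analysis uses the increase in the proportion of
#' patients in clinical remission over the 24-week follow-up; the
#' cost-utility analysis uses QALYs computed from EQ-5D utility indexes.
#' Remission is disease-specific: Harvey-Bradshaw index of 4 or less for
#' Crohn disease; Simple Clinical Colitis Activity Index and partial Mayo
#' score each of 2 or less for ulcerative colitis.
#'
#' @name effect_model
NULL

#' Remission thresholds per disease
#' @export
remission_thresholds <- function() c(CD = 4, UC = 2)

#' Classify clinical remission from activity scores
#'
#' Crohn disease: score (HBI) of 4 or less. Ulcerative colitis: score
#' (SCCAI) of 2 or less and, when a second index (partial Mayo) is
#' recorded, that too must be 2 or less; when only one UC index is recorded
#' the recorded one is used. A fully missing score yields `NA` (to be
#' imputed).
#'
#' @param disease `"CD"` or `"UC"` (vectorised).
#' @param score HBI (CD) or SCCAI (UC) score, >= 0.
#' @param second_score partial Mayo score for UC patients, or `NA`.
#' @return Logical vector; `NA` where all relevant scores are missing.
#' @export
#' @examples
#' classify_remission("CD", 4) # TRUE
#' classify_remission("UC", 3) # FALSE
classify_remission <- function(disease, score, second_score = NA) {
  n <- max(length(disease), length(score), length(second_score))
  disease <- rep_len(disease, n)
  score <- rep_len(score, n)
  second_score <- rep_len(second_score, n)
  if (!all(disease %in% c("CD", "UC"))) {
    stop("disease must be 'CD' or 'UC'", call. = FALSE)
  }
  if (any(score < 0, na.rm = TRUE) || any(second_score < 0, na.rm = TRUE)) {
    stop("activity scores must be >= 0", call. = FALSE)
  }
  thr <- remission_thresholds()[disease]
  first <- score <= thr
  second <- second_score <= thr
  out <- ifelse(disease == "CD",
                first,
                ifelse(is.na(first), second,
                       ifelse(is.na(second), first, first & second)))
  unname(out)
}

.remission_at <- function(patients, week) {
  w <- paste0("_", week)
  ifelse(patients$disease == "CD",
         classify_remission("CD", patients[[paste0("hbi", w)]]),
         classify_remission("UC", patients[[paste0("sccai", w)]],
                            patients[[paste0("pmayo", w)]]))
}

#' QALYs from an EQ-5D utility change
#'
#' Gained-QALY convention used throughout: the utility improvement over the
#' follow-up times the horizon in years, i.e. `(eq5d_w24 - eq5d_w0) *
#' horizon_years`. An area-under-the-curve alternative (mean of the two
#' utilities times the horizon, i.e. absolute rather than incremental
#' QALYs) is available via `convention = "auc"` for sensitivity use.
#'
#' @param eq5d_w0,eq5d_w24 utility indexes in \[-1, 1\]; `NA` propagates.
#' @param horizon_years horizon in years (> 0; default 0.5 for 24 weeks).
#' @param convention `"gained"` (default) or `"auc"`.
#' @return QALYs.
#' @export
#' @examples
#' qaly(0.816, 1.00) # 0.092
#' qaly(0.825, 1.00) # 0.0875
qaly <- function(eq5d_w0, eq5d_w24, horizon_years = 0.5,
                 convention = c("gained", "auc")) {
  convention <- match.arg(convention)
  if (any(horizon_years <= 0)) {
    stop("'horizon_years' must be > 0", call. = FALSE)
  }
  if (any(abs(eq5d_w0) > 1, na.rm = TRUE) ||
      any(abs(eq5d_w24) > 1, na.rm = TRUE)) {
    stop("utilities must be in [-1, 1]", call. = FALSE)
  }
  if (convention == "gained") {
    (eq5d_w24 - eq5d_w0) * horizon_years
  } else {
    (eq5d_w0 + eq5d_w24) / 2 * horizon_years
  }
}

#' Per-patient effect summaries
#'
#' Computes remission status at each visit, weeks in remission
#' (piecewise-constant expansion of visit statuses, matching the cost
#' expansion: the week-12 status covers weeks 1--12 and the week-24 status
#' weeks 13--24), and QALYs.
#'
#' @param patients a `cea_patients` data frame.
#' @param horizon_years QALY horizon in years.
#' @param qaly_convention passed to [qaly()].
#' @return A data frame of class `cea_effects` with columns `patient_id`,
#'   `arm`, `in_remission_w0/w12/w24`, `weeks_in_remission`, `eq5d_w0`,
#'   `eq5d_w24` and `qaly`.
#' @export
effect_summary <- function(patients, horizon_years = 0.5,
                           qaly_convention = "gained") {
  patients <- validate_patients(patients)
  rem0 <- .remission_at(patients, "w0")
  rem12 <- .remission_at(patients, "w12")
  rem24 <- .remission_at(patients, "w24")
  out <- data.frame(
    patient_id = patients$patient_id,
    arm = patients$arm,
    in_remission_w0 = rem0,
    in_remission_w12 = rem12,
    in_remission_w24 = rem24,
    weeks_in_remission = interval_expand(NA, as.numeric(rem12),
                                         as.numeric(rem24)),
    eq5d_w0 = patients$eq5d_w0,
    eq5d_w24 = patients$eq5d_w24,
    qaly = qaly(patients$eq5d_w0, patients$eq5d_w24, horizon_years,
                qaly_convention),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("cea_effects", "data.frame"))
}

#' Increase in the proportion of patients in remission
#'
#' `(number in remission at week 24 - number in remission at week 0) / n`
#' for a group of patients.
#'
#' @param effects a `cea_effects` data frame (one group).
#' @return A proportion in \[-1, 1\].
#' @export
#' @examples
#' # 10/21 in remission at baseline, 17/21 at week 24 -> 1/3
remission_increase <- function(effects) {
  if (nrow(effects) == 0) stop("empty group", call. = FALSE)
  (sum(effects$in_remission_w24) - sum(effects$in_remission_w0)) /
    nrow(effects)
}

#' Incremental effect between two groups
#'
#' `measure(group A) - measure(group B)`, where the measure is either the
#' remission-increase proportion or the mean QALY gain.
#'
#' @param effects_a,effects_b `cea_effects` data frames for the two groups.
#' @param measure `"remission_increase"` or `"qaly_mean"`.
#' @return The difference in the chosen measure.
#' @export
incremental_effect <- function(effects_a, effects_b,
                               measure = c("remission_increase",
                                           "qaly_mean")) {
  measure <- match.arg(measure)
  if (nrow(effects_a) == 0 || nrow(effects_b) == 0) {
    stop("empty group", call. = FALSE)
  }
  f <- switch(measure,
              remission_increase = remission_increase,
              qaly_mean = function(e) mean(e$qaly))
  f(effects_a) - f(effects_b)
}
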