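#' Societal cost accounting
#'
#' Per-patient costs over the 24-week horizon are built up from three
#' categories, following the societal perspective: health-care costs
#' (resource counts times official unit rates, plus the per-contact
#' telemonitoring rate derived from provider time), equipment costs (flat
#' platform rental), and productivity and leisure costs valued by the
#' human-capital approach (WPAI-derived hours times the gross hourly wage,
#' telemonitoring contact time valued at the leisure rate). No discounting
#' is applied at this horizon.
#'
#' @name cost_model
NULL

#' Per-contact cost of a telemonitoring contact
#'
#' There is no official tariff for telemonitoring contacts, so the rate is
#' constructed as provider time per contact times the provider's salary per
#' minute.
#'
#' @param minutes mean provider minutes per contact (> 0).
#' @param salary_per_min provider salary in EUR per minute (> 0).
#' @return Cost per contact in EUR.
#' @export
#' @examples
#' telemonitoring_contact_cost(8, 0.21) # 1.68 (nurse)
#' telemonitoring_contact_cost(8, 0.38) # 3.04 (physician)
telemonitoring_contact_cost <- function(minutes, salary_per_min) {
  if (!is.numeric(minutes) || any(minutes <= 0)) {
    stop("'minutes' must be > 0", call. = FALSE)
  }
  if (!is.numeric(salary_per_min) || any(salary_per_min <= 0)) {
    stop("'salary_per_min' must be > 0", call. = FALSE)
  }
  minutes * salary_per_min
}

#' Equipment (platform rental) cost
#'
#' @param months months of platform rental, between 0 and the trial horizon.
#' @param rate rental rate in EUR per patient-month.
#' @param horizon_months trial horizon in months (default 6).
#' @return Cost in EUR.
#' @export
#' @examples
#' equipment_cost(6, 3.99) # 23.94
equipment_cost <- function(months, rate, horizon_months = 6) {
  if (any(months < 0) || any(months > horizon_months)) {
    stop("'months' must be between 0 and the trial horizon (",
         horizon_months, " months)", call. = FALSE)
  }
  months * rate
}

#' Cost of work hours lost (absenteeism valuation)
#'
#' Values lost work hours at the gross hourly wage (human-capital approach).
#' Also used to cost presenteeism-equivalent hours.
#'
#' @param hours_missed hours lost (>= 0); `NA` propagates.
#' @param wage hourly wage in EUR.
#' @param not_working logical; a patient not in employment accrues no wage
#'   loss, regardless of the hours fields.
#' @return Cost in EUR.
#' @export
absenteeism_cost <- function(hours_missed, wage, not_working = FALSE) {
  if (any(hours_missed < 0, na.rm = TRUE)) {
    stop("'hours_missed' must be >= 0", call. = FALSE)
  }
  ifelse(rep_len(not_working, length(hours_missed)), 0, hours_missed * wage)
}

#' Presenteeism-equivalent hours lost
#'
#' WPAI convention: percentage impairment while working (Q5) times hours
#' actually worked in the past 7 days (Q4). The result is capped at
#' `hours_worked` (one cannot lose more hours than one worked).
#'
#' @param work_impairment_pct impairment percentage, 0--100.
#' @param hours_worked hours worked over the past 7 days.
#' @return Equivalent hours lost; cost these via [absenteeism_cost()].
#' @export
presenteeism_hours <- function(work_impairment_pct, hours_worked) {
  if (any(work_impairment_pct < 0 | work_impairment_pct > 100,
          na.rm = TRUE)) {
    stop("'work_impairment_pct' must be in [0, 100]", call. = FALSE)
  }
  pmin(work_impairment_pct / 100 * hours_worked, hours_worked)
}

#' Cost of work absence for in-person medical visits
#'
#' Each in-person visit (outpatient or emergency) is assumed to cost a fixed
#' number of lost hours (default 3.3 h/visit), valued at the wage.
#' Telemonitoring contacts are instead valued as leisure time, and telephone
#' contacts use their actual duration fraction; see [total_cost()].
#'
#' @param n_visits number of in-person visits.
#' @param wage hourly wage in EUR.
#' @param hours_per_visit hours lost per visit.
#' @return Cost in EUR.
#' @export
visit_absence_cost <- function(n_visits, wage, hours_per_visit = 3.3) {
  if (any(n_visits < 0, na.rm = TRUE)) {
    stop("'n_visits' must be >= 0", call. = FALSE)
  }
  n_visits * hours_per_visit * wage
}

#' Cost of impaired social/leisure activities
#'
#' WPAI Q6 percentage impairment of regular activities applied to a weekly
#' base of leisure hours at risk, valued at the leisure rate.
#'
#' @param social_impairment_pct impairment percentage, 0--100.
#' @param leisure_hours_base leisure hours at risk (>= 0).
#' @param leisure_rate EUR per leisure hour.
#' @return Cost in EUR.
#' @export
leisure_impairment_cost <- function(social_impairment_pct,
                                    leisure_hours_base, leisure_rate) {
  if (any(social_impairment_pct < 0 | social_impairment_pct > 100,
          na.rm = TRUE)) {
    stop("'social_impairment_pct' must be in [0, 100]", call. = FALSE)
  }
  if (any(leisure_hours_base < 0)) {
    stop("'leisure_hours_base' must be >= 0", call. = FALSE)
  }
  social_impairment_pct / 100 * leisure_hours_base * leisure_rate
}

#' Expand weekly assessments to a 24-week total
#'
#' WPAI responses have a 7-day recall but are assessed at weeks 0, 12 and
#' 24. Weekly values are expanded piecewise-constant over the preceding
#' interval: the week-12 assessment covers weeks 1--12, the week-24
#' assessment covers weeks 13--24. The baseline assessment describes the
#' pre-study week and is not costed into the study total. If one follow-up
#' assessment is missing the other is carried across; if both are missing
#' the result is `NA` (to be imputed).
#'
#' @param w0,w12,w24 weekly values at each assessment (vectors recycle).
#' @return 24-week totals: `12 * w12 + 12 * w24`.
#' @export
#' @examples
#' interval_expand(0, 50, 0) # 600: week-12 value covers weeks 1-12
interval_expand <- function(w0, w12, w24) {
  v12 <- ifelse(is.na(w12), w24, w12)
  v24 <- ifelse(is.na(w24), w12, w24)
  12 * v12 + 12 * v24
}

.hc_fields <- c("emergency", "outpatient", "hospitalization",
                "surgery_hospitalization", "phone_calls", "tm_contacts")
.prod_fields <- c("absenteeism", "presenteeism", "visit_absence",
                  "call_absence", "leisure_tm", "leisure_impairment")

#' Health-care cost fields for resource-use counts
#'
#' Multiplies each resource count by its unit rate. Telemonitoring contacts
#' are costed per provider type via [telemonitoring_contact_cost()].
#'
#' @param patients a `cea_patients` data frame (resource columns used).
#' @param costs a `cea_unit_costs` table.
#' @return Data frame with the six health-care cost fields per patient.
#' @export
healthcare_cost <- function(patients, costs) {
  nurse_contact <- telemonitoring_contact_cost(costs$contact_minutes,
                                               costs$nurse_salary_per_min)
  phys_contact <- telemonitoring_contact_cost(costs$contact_minutes,
                                              costs$physician_salary_per_min)
  data.frame(
    emergency = patients$emergency_visits * costs$emergency_visit,
    outpatient = patients$outpatient_visits * costs$outpatient_visit,
    hospitalization = patients$hospital_days * costs$hospital_day,
    surgery_hospitalization =
      patients$surgical_days * costs$surgical_hospital_day,
    phone_calls = patients$phone_nurse * costs$phone_call_nurse +
      patients$phone_physician * costs$phone_call_physician,
    tm_contacts = patients$tm_nurse * nurse_contact +
      patients$tm_physician * phys_contact
  )
}

#' Full per-patient societal cost breakdown
#'
#' Computes every cost category for each (fully observed or imputed) patient
#' and the category totals. The sum invariants always hold:
#' `total_healthcare` is the six health-care fields plus equipment,
#' `total_productivity` is the six productivity/leisure fields, and `total`
#' is their sum. An optional inflation multiplier from the unit-cost table
#' scales all costs uniformly.
#'
#' Valuation rules: WPAI absenteeism (Q2) and presenteeism (Q5 x Q4, capped)
#' hours are expanded piecewise-constant over the follow-up and valued at
#' the sex- and age-specific wage for employed patients only. Time lost to
#' in-person visits (3.3 h/visit) and to telephone contacts (their call
#' duration), assumed to fall in working hours, is valued at the wage for
#' all patients; patient time in telemonitoring contacts is assumed out of
#' office hours and valued at the leisure rate.
#'
#' @param patients a `cea_patients` data frame with no unimputed missing
#'   cost fields.
#' @param costs a `cea_unit_costs` table.
#' @return A data frame of class `cea_costs`: one row per patient with
#'   `patient_id`, `arm`, every cost field and the three totals (EUR).
#' @export
total_cost <- function(patients, costs = default_unit_costs()) {
  patients <- validate_patients(patients)
  costs <- validate_unit_costs(costs)
  hc <- healthcare_cost(patients, costs)
  need <- c(.count_cols, "tm_months",
            paste0("wpai_hours_missed_w", c(12, 24)),
            paste0("wpai_hours_worked_w", c(12, 24)),
            paste0("wpai_work_impair_w", c(12, 24)),
            paste0("wpai_social_impair_w", c(12, 24)))
  nmiss <- colSums(is.na(as.data.frame(patients)[, need, drop = FALSE]))
  if (any(nmiss > 0)) {
    stop("cost fields still missing (run imputation first): ",
         paste(names(nmiss)[nmiss > 0], collapse = ", "), call. = FALSE)
  }

  wage <- lookup_wage(costs, patients$sex, patients$age_years)
  nw12 <- patients$wpai_not_working_w12
  nw24 <- patients$wpai_not_working_w24

  abs_h <- function(w, nw) {
    ifelse(nw, 0, patients[[paste0("wpai_hours_missed_", w)]])
  }
  pres_h <- function(w, nw) {
    ifelse(nw, 0,
           presenteeism_hours(patients[[paste0("wpai_work_impair_", w)]],
                              patients[[paste0("wpai_hours_worked_", w)]]))
  }
  absenteeism <- interval_expand(NA, abs_h("w12", nw12),
                                 abs_h("w24", nw24)) * wage
  presenteeism <- interval_expand(NA, pres_h("w12", nw12),
                                  pres_h("w24", nw24)) * wage

  in_person <- patients$outpatient_visits + patients$emergency_visits
  visit_absence <- visit_absence_cost(in_person, wage,
                                      costs$visit_absence_hours)
  calls <- patients$phone_nurse + patients$phone_physician
  call_absence <- calls * costs$call_minutes / 60 * wage
  tm_contacts_n <- patients$tm_nurse + patients$tm_physician
  leisure_tm <- tm_contacts_n * costs$tm_patient_minutes / 60 *
    costs$leisure_hour
  # weekly Q6 impairment of the weekly leisure-hours base, expanded over
  # the 24-week horizon like the other WPAI quantities
  leisure_impairment <- interval_expand(
    NA,
    leisure_impairment_cost(patients$wpai_social_impair_w12,
                            costs$leisure_hours_base, costs$leisure_hour),
    leisure_impairment_cost(patients$wpai_social_impair_w24,
                            costs$leisure_hours_base, costs$leisure_hour))

  out <- data.frame(patient_id = patients$patient_id, arm = patients$arm,
                    hc, stringsAsFactors = FALSE)
  out$equipment <- equipment_cost(patients$tm_months,
                                  costs$tm_rental_per_patient_month,
                                  costs$horizon_months)
  out$absenteeism <- absenteeism
  out$presenteeism <- presenteeism
  out$visit_absence <- visit_absence
  out$call_absence <- call_absence
  out$leisure_tm <- leisure_tm
  out$leisure_impairment <- leisure_impairment
  infl <- costs$inflation_multiplier
  for (f in c(.hc_fields, "equipment", .prod_fields)) out[[f]] <- out[[f]] * infl
  out$total_healthcare <- unname(rowSums(out[, c(.hc_fields, "equipment")]))
  out$total_productivity <- unname(rowSums(out[, .prod_fields]))
  out$total <- out$total_healthcare + out$total_productivity
  structure(out, class = c("cea_costs", "data.frame"))
}

#' Cost field groups of a cost breakdown
#'
#' @return Character vectors of column names.
#' @export
cost_fields <- function() {
  list(healthcare = c(.hc_fields, "equipment"), productivity = .prod_fields,
       totals = c("total_healthcare", "total_productivity", "total"))
}
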