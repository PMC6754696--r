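#' Unit cost tables
#'
#' A unit cost table holds the price weights used to turn resource counts and
#' WPAI-derived hours into euros: official per-unit health-care rates, the
#' telemonitoring platform rental rate, provider salaries per minute (used to
#' derive the per-contact telemonitoring rate), the gross-wage lookup table
#' used by the human-capital valuation of lost work time, and the leisure-hour
#' rate. All computation is carried out in EUR; `eur_to_usd` is applied only
#' at report time.
#'
#' @name unit_costs
NULL

#' Default unit cost table
#'
#' Returns the packaged default price weights: 2016 Spanish regional tariffs
#' for health-care resources, the telemonitoring platform rental rate, nurse
#' and physician salaries per minute, an hourly gross-wage table by sex and
#' 10-year age band (within the declared 12.04--25.23 EUR/h range; the
#' official sex-by-age values are not public at this granularity, so the
#' table is user-replaceable config), and the leisure-time rate.
#'
#' @return An object of class `cea_unit_costs` (a named list).
#' @export
#' @examples
#' uc <- default_unit_costs()
#' uc$outpatient_visit # 40.02
default_unit_costs <- function() {
  costs <- list(
    emergency_visit = 189,
    outpatient_visit = 40.02,
    hospital_day = 310.17,
    surgical_hospital_day = 378,
    phone_call_nurse = 15,
    phone_call_physician = 21.47,
    contact_minutes = 8,
    nurse_salary_per_min = 0.21,
    physician_salary_per_min = 0.38,
    tm_rental_per_patient_month = 3.99,
    horizon_months = 6,
    leisure_hour = 9.18,
    visit_absence_hours = 3.3,
    call_minutes = 10,
    tm_patient_minutes = 5,
    leisure_hours_base = 0,
    inflation_multiplier = 1,
    eur_to_usd = 1.09465,
    wage_table = list(
      # lower bounds of age bands; last band is open-ended
      age_bands = c(18, 30, 40, 50, 60),
      M = c(13.50, 15.20, 16.80, 18.00, 18.50),
      F = c(12.04, 13.40, 14.60, 15.80, 16.20),
      min = 12.04,
      max = 25.23
    )
  )
  validate_unit_costs(costs)
}

# keys that must be strictly positive rates
.rate_keys <- c(
  "emergency_visit", "outpatient_visit", "hospital_day",
  "surgical_hospital_day", "phone_call_nurse", "phone_call_physician",
  "contact_minutes", "nurse_salary_per_min", "physician_salary_per_min",
  "tm_rental_per_patient_month", "leisure_hour", "visit_absence_hours",
  "call_minutes", "tm_patient_minutes", "eur_to_usd", "horizon_months",
  "inflation_multiplier"
)

#' Validate a unit cost table
#'
#' Checks that every rate is strictly positive, that optional quantities
#' (`leisure_hours_base`) are non-negative, and that the wage table is
#' consistent with its declared minimum and maximum.
#'
#' @param costs a named list of unit costs (see [default_unit_costs()]).
#' @return The validated table, classed `cea_unit_costs`.
#' @export
validate_unit_costs <- function(costs) {
  stopifnot(is.list(costs))
  missing_keys <- setdiff(c(.rate_keys, "leisure_hours_base", "wage_table"),
                          names(costs))
  if (length(missing_keys) > 0) {
    stop("unit cost table is missing mandatory key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  for (k in .rate_keys) {
    v <- costs[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("unit cost '", k, "' must be a single positive number, got: ",
           deparse(costs[[k]]), call. = FALSE)
    }
  }
  if (!is.numeric(costs$leisure_hours_base) || costs$leisure_hours_base < 0) {
    stop("'leisure_hours_base' must be >= 0", call. = FALSE)
  }
  wt <- costs$wage_table
  if (!is.list(wt) ||
      !all(c("age_bands", "M", "F", "min", "max") %in% names(wt))) {
    stop("'wage_table' must contain age_bands, M, F, min and max",
         call. = FALSE)
  }
  if (length(wt$M) != length(wt$age_bands) ||
      length(wt$F) != length(wt$age_bands)) {
    stop("wage_table M/F vectors must match the number of age bands",
         call. = FALSE)
  }
  if (is.unsorted(wt$age_bands, strictly = TRUE)) {
    stop("wage_table age_bands must be strictly increasing", call. = FALSE)
  }
  wages <- c(wt$M, wt$F)
  if (any(wages < wt$min - 1e-9) || any(wages > wt$max + 1e-9)) {
    stop("wage_table values must lie within the declared min/max (",
         wt$min, "-", wt$max, ")", call. = FALSE)
  }
  if (any(wages <= 0)) stop("wages must be positive", call. = FALSE)
  structure(costs, class = "cea_unit_costs")
}

#' Read a unit cost configuration file
#'
#' Reads a YAML unit-cost configuration. Keys absent from the file take the
#' packaged defaults (see [default_unit_costs()]); present keys override
#' them. The merged table is validated before it is returned, so e.g. a
#' non-positive rate in the file is an error.
#'
#' @param path path to a YAML file.
#' @return A validated `cea_unit_costs` object.
#' @export
read_unit_costs <- function(path) {
  if (!file.exists(path)) stop("unit cost file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("unit cost file must be a YAML mapping",
                           call. = FALSE)
  costs <- unclass(default_unit_costs())
  for (k in names(user)) {
    if (k == "wage_table") {
      for (wk in names(user$wage_table)) {
        costs$wage_table[[wk]] <- user$wage_table[[wk]]
      }
    } else {
      costs[[k]] <- user[[k]]
    }
  }
  validate_unit_costs(costs)
}

#' Write a unit cost table to YAML
#'
#' @param costs a `cea_unit_costs` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_unit_costs <- function(costs, path) {
  costs <- validate_unit_costs(costs)
  yaml::write_yaml(unclass(costs), path)
  invisible(path)
}

#' Hourly gross wage by sex and age
#'
#' Looks up the human-capital hourly wage used to value lost work time.
#'
#' @param costs a `cea_unit_costs` object.
#' @param sex character vector, `"M"` or `"F"`.
#' @param age_years numeric vector of ages (>= 18).
#' @return Numeric vector of hourly wages in EUR.
#' @export
lookup_wage <- function(costs, sex, age_years) {
  wt <- costs$wage_table
  stopifnot(length(sex) == length(age_years))
  band <- findInterval(age_years, wt$age_bands)
  if (any(band == 0)) {
    stop("age below the youngest wage band (", wt$age_bands[1], ")",
         call. = FALSE)
  }
  ifelse(sex == "M", wt$M[band], wt$F[band])
}

#' Convert euro amounts to US dollars at the report-time exchange rate
#'
#' @param x numeric euro amounts.
#' @param costs a `cea_unit_costs` object supplying `eur_to_usd`.
#' @return Numeric USD amounts.
#' @export
eur_to_usd <- function(x, costs = default_unit_costs()) {
  x * costs$eur_to_usd
}

#' @export
print.cea_unit_costs <- function(x, ...) {
  cat("Unit cost table (EUR", paste0("; 1 EUR = ", x$eur_to_usd, " USD)\n"))
  cat(sprintf("  emergency visit %8.2f   outpatient visit %8.2f\n",
              x$emergency_visit, x$outpatient_visit))
  cat(sprintf("  hospital day    %8.2f   surgical day     %8.2f\n",
              x$hospital_day, x$surgical_hospital_day))
  cat(sprintf("  phone (nurse)   %8.2f   phone (physician)%8.2f\n",
              x$phone_call_nurse, x$phone_call_physician))
  cat(sprintf("  telemonitoring contact: %d min at %.2f/%.2f EUR/min (nurse/physician)\n",
              as.integer(x$contact_minutes), x$nurse_salary_per_min,
              x$physician_salary_per_min))
  cat(sprintf("  platform rental %.2f EUR/patient-month; leisure hour %.2f EUR\n",
              x$tm_rental_per_patient_month, x$leisure_hour))
  cat(sprintf("  wages %.2f-%.2f EUR/h by sex and age band\n",
              x$wage_table$min, x$wage_table$max))
  invisible(x)
}
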