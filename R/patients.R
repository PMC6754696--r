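#' Patient-level trial data
#'
#' Patient records are stored flat: one row per patient, repeated-measure
#' columns suffixed `_w0` / `_w12` / `_w24`, missing values as empty CSV
#' cells (`NA` in R). This keeps the pipeline diff-able and every stage
#' independently testable.
#'
#' Columns:
#' \describe{
#'   \item{patient_id}{opaque string identifier}
#'   \item{arm}{`control`, `telephone` or `telemonitoring`}
#'   \item{disease}{`CD` (Crohn disease) or `UC` (ulcerative colitis)}
#'   \item{age_years, sex, employed}{demographics; `sex` is `M`/`F`}
#'   \item{hbi_w0/hbi_w12/hbi_w24}{Harvey-Bradshaw index (CD only)}
#'   \item{sccai_*, pmayo_*}{Simple Clinical Colitis Activity Index and
#'     partial Mayo score (UC only)}
#'   \item{eq5d_w0, eq5d_w24}{EQ-5D utility index, in \[-1, 1\]}
#'   \item{wpai_hours_missed_*, wpai_hours_worked_*}{WPAI Q2/Q4 hours over
#'     the past 7 days}
#'   \item{wpai_work_impair_*, wpai_social_impair_*}{WPAI Q5/Q6 percentage
#'     impairment, 0--100}
#'   \item{wpai_not_working_*}{WPAI employment item; implies zero worked
#'     hours}
#'   \item{emergency_visits, outpatient_visits, hospital_days,
#'     surgical_days, phone_nurse, phone_physician}{resource-use counts over
#'     the 24-week horizon}
#'   \item{tm_nurse, tm_physician, tm_months}{telemonitoring contacts by
#'     provider and months of platform rental; zero outside the
#'     telemonitoring arm}
#'   \item{calpro_w0, calpro_w24}{fecal calprotectin (ug/g), carried as a
#'     correlated covariate; enters no cost or effect computation}
#' }
#'
#' @name patient_data
NULL

#' Trial arm labels
#' @export
cea_arms <- function() c("control", "telephone", "telemonitoring")

.weeks <- c("w0", "w12", "w24")

#' Column schema for patient-level CSV files
#'
#' @return Named character vector mapping column name to type
#'   (`character`, `integer`, `numeric`, `logical`).
#' @export
patient_schema <- function() {
  cols <- c(
    patient_id = "character", arm = "character", disease = "character",
    age_years = "integer", sex = "character", employed = "logical"
  )
  for (w in .weeks) {
    cols[paste0("hbi_", w)] <- "integer"
    cols[paste0("sccai_", w)] <- "integer"
    cols[paste0("pmayo_", w)] <- "integer"
  }
  cols["eq5d_w0"] <- "numeric"
  cols["eq5d_w24"] <- "numeric"
  for (w in .weeks) {
    cols[paste0("wpai_hours_missed_", w)] <- "numeric"
    cols[paste0("wpai_hours_worked_", w)] <- "numeric"
    cols[paste0("wpai_work_impair_", w)] <- "numeric"
    cols[paste0("wpai_social_impair_", w)] <- "numeric"
    cols[paste0("wpai_not_working_", w)] <- "logical"
  }
  cols[c("emergency_visits", "outpatient_visits", "hospital_days",
         "surgical_days", "phone_nurse", "phone_physician",
         "tm_nurse", "tm_physician")] <- "integer"
  cols["tm_months"] <- "numeric"
  cols["calpro_w0"] <- "numeric"
  cols["calpro_w24"] <- "numeric"
  cols
}

.count_cols <- c("emergency_visits", "outpatient_visits", "hospital_days",
                 "surgical_days", "phone_nurse", "phone_physician",
                 "tm_nurse", "tm_physician")
.tm_cols <- c("tm_nurse", "tm_physician", "tm_months")

.located_stop <- function(row, col, msg) {
  stop(sprintf("patient record %s, column '%s': %s", row, col, msg),
       call. = FALSE)
}

#' Validate a patient-record table
#'
#' Enforces the record invariants: arm/disease always present and known, age
#' at least 18, percentages within 0--100, hours and counts non-negative,
#' utilities within \[-1, 1\], `not_working` implying zero worked hours,
#' telemonitoring-specific fields zero outside the telemonitoring arm, and
#' disease-appropriate activity indexes. Week-12/24 fields may be missing
#' (they are imputable); malformed values are rejected with the offending
#' row and column named, never silently coerced.
#'
#' @param patients a data frame following [patient_schema()].
#' @return The validated data frame, classed `cea_patients`.
#' @export
validate_patients <- function(patients) {
  stopifnot(is.data.frame(patients))
  schema <- patient_schema()
  missing_cols <- setdiff(names(schema), names(patients))
  if (length(missing_cols) > 0) {
    stop("patient table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  patients <- as.data.frame(patients)[, names(schema)]
  n <- nrow(patients)
  if (n == 0) return(structure(patients, class = c("cea_patients",
                                                   "data.frame")))
  rowid <- ifelse(is.na(patients$patient_id),
                  paste0("#", seq_len(n)), patients$patient_id)

  chk <- function(col, bad, msg) {
    bad <- which(bad)
    if (length(bad) > 0) .located_stop(rowid[bad[1]], col, msg)
  }
  chk("arm", is.na(patients$arm) | !(patients$arm %in% cea_arms()),
      "unknown or missing arm code")
  chk("disease", is.na(patients$disease) |
        !(patients$disease %in% c("CD", "UC")),
      "unknown or missing disease code")
  chk("sex", is.na(patients$sex) | !(patients$sex %in% c("M", "F")),
      "sex must be 'M' or 'F'")
  chk("age_years", is.na(patients$age_years) | patients$age_years < 18,
      "age must be a number >= 18")
  chk("employed", is.na(patients$employed), "employed must be TRUE/FALSE")
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicated patient_id: ",
         patients$patient_id[duplicated(patients$patient_id)][1],
         call. = FALSE)
  }

  is_cd <- patients$disease == "CD"
  for (w in .weeks) {
    for (idx in c("hbi", "sccai", "pmayo")) {
      col <- paste0(idx, "_", w)
      v <- patients[[col]]
      chk(col, !is.na(v) & v < 0, "activity score must be >= 0")
      wrong_disease <- if (idx == "hbi") !is_cd else is_cd
      chk(col, !is.na(v) & wrong_disease,
          paste0("score not defined for disease ",
                 ifelse(idx == "hbi", "UC", "CD")))
    }
    for (col in paste0(c("wpai_hours_missed_", "wpai_hours_worked_"), w)) {
      chk(col, !is.na(patients[[col]]) & patients[[col]] < 0,
          "hours must be >= 0")
    }
    for (col in paste0(c("wpai_work_impair_", "wpai_social_impair_"), w)) {
      v <- patients[[col]]
      chk(col, !is.na(v) & (v < 0 | v > 100),
          "percentage impairment must be in [0, 100]")
    }
    nw <- patients[[paste0("wpai_not_working_", w)]]
    hw <- patients[[paste0("wpai_hours_worked_", w)]]
    chk(paste0("wpai_hours_worked_", w),
        !is.na(nw) & nw & !is.na(hw) & hw > 0,
        "not_working implies zero hours worked")
  }
  for (col in c("eq5d_w0", "eq5d_w24")) {
    v <- patients[[col]]
    chk(col, !is.na(v) & (v < -1 | v > 1), "utility must be in [-1, 1]")
  }
  for (col in .count_cols) {
    v <- patients[[col]]
    chk(col, !is.na(v) & (v < 0 | v != round(v)),
        "count must be a non-negative integer")
  }
  chk("tm_months", !is.na(patients$tm_months) &
        (patients$tm_months < 0 | patients$tm_months > 6),
      "tm_months must be in [0, 6]")
  not_tm <- patients$arm != "telemonitoring"
  for (col in .tm_cols) {
    chk(col, not_tm & !is.na(patients[[col]]) & patients[[col]] != 0,
        "telemonitoring fields must be 0 outside the telemonitoring arm")
  }
  structure(patients, class = c("cea_patients", "data.frame"))
}

#' Read patient-level trial data from CSV
#'
#' Missing week-12/24 entries (empty cells) are kept as `NA` and flagged for
#' imputation, never coerced to zero. Malformed rows are rejected with an
#' error naming the row and column.
#'
#' @param path path to a CSV file following [patient_schema()].
#' @param schema_version schema identifier; only `"1"` is understood.
#' @return A validated `cea_patients` data frame.
#' @export
read_patients <- function(path, schema_version = "1") {
  if (!identical(as.character(schema_version), "1")) {
    stop("unknown patient schema version: ", schema_version, call. = FALSE)
  }
  if (!file.exists(path)) stop("patient file not found: ", path,
                               call. = FALSE)
  schema <- patient_schema()
  header <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  missing_cols <- setdiff(names(schema), header)
  if (length(missing_cols) > 0) {
    stop("patient file header is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "")
  out <- raw[, names(schema), drop = FALSE]
  for (col in names(schema)) {
    v <- out[[col]]
    out[[col]] <- switch(
      schema[[col]],
      character = v,
      integer = .parse_num(v, col, integer = TRUE),
      numeric = .parse_num(v, col, integer = FALSE),
      logical = .parse_logical(v, col)
    )
  }
  validate_patients(out)
}

.parse_num <- function(v, col, integer) {
  parsed <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(parsed))
  if (length(bad) > 0) {
    .located_stop(bad[1], col, paste0("not a number: '", v[bad[1]], "'"))
  }
  if (integer) {
    frac <- which(!is.na(parsed) & parsed != round(parsed))
    if (length(frac) > 0) {
      .located_stop(frac[1], col, paste0("not an integer: '", v[frac[1]], "'"))
    }
    parsed <- as.integer(round(parsed))
  }
  parsed
}

.parse_logical <- function(v, col) {
  up <- toupper(trimws(v))
  res <- rep(NA, length(v))
  res[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  res[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(!is.na(v) & is.na(res))
  if (length(bad) > 0) {
    .located_stop(bad[1], col, paste0("not a logical: '", v[bad[1]], "'"))
  }
  res
}

#' Write patient-level trial data to CSV
#'
#' Round-trips exactly through [read_patients()]: missing values are written
#' as empty cells and all numeric values at full precision.
#'
#' @param patients a `cea_patients` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  patients <- validate_patients(patients)
  utils::write.csv(patients, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.cea_patients <- function(x, ...) {
  cat("Patient-level trial data:", nrow(x), "patients\n")
  if (nrow(x) > 0) print(table(arm = x$arm, disease = x$disease))
  n_miss <- sum(is.na(as.data.frame(x)[
    , grep("_w(12|24)$", names(x), value = TRUE)]))
  cat("missing week-12/24 cells:", n_miss, "\n")
  invisible(x)
}
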