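test_that("telemonitoring contact rate is provider minutes times salary", {
  expect_equal(telemonitoring_contact_cost(8, 0.21), 1.68)
  expect_equal(telemonitoring_contact_cost(8, 0.38), 3.04)
  expect_error(telemonitoring_contact_cost(0, 0.21), "minutes")
  expect_error(telemonitoring_contact_cost(8, -1), "salary")
})

test_that("equipment cost is months of rental within the horizon", {
  expect_equal(equipment_cost(6, 3.99), 23.94)
  expect_equal(equipment_cost(0, 3.99), 0)
  # USD-mode rate reproduces the printed dollar cell to cent rounding
  expect_equal(round(equipment_cost(6, 3.99) * 1.09465, 2), 26.21)
  expect_error(equipment_cost(7, 3.99), "horizon")
})

test_that("hour-valuation operations follow the WPAI costing rules", {
  expect_equal(absenteeism_cost(10, 12.04), 120.40)
  expect_equal(absenteeism_cost(0, 25), 0)
  expect_equal(absenteeism_cost(10, 25, not_working = TRUE), 0)

  expect_equal(presenteeism_hours(50, 40), 20)
  expect_equal(presenteeism_hours(0, 40), 0)
  expect_equal(presenteeism_hours(100, 35), 35)
  expect_error(presenteeism_hours(120, 10), "0, 100")

  expect_equal(visit_absence_cost(2, 15, 3.3), 99.00)
  expect_equal(visit_absence_cost(0, 15, 3.3), 0)

  expect_equal(leisure_impairment_cost(0, 10, 9.18), 0)
  expect_equal(leisure_impairment_cost(100, 10, 9.18), 91.80)
  expect_equal(leisure_impairment_cost(35, 20, 9.18), 64.26)
})

test_that("weekly assessments expand piecewise-constant over the horizon", {
  expect_equal(interval_expand(5, 2, 2), 48) # identical follow-ups: 24x
  expect_equal(interval_expand(0, 0, 0), 0)
  expect_equal(interval_expand(NA, 50, 0), 600) # w12 covers weeks 1-12
  # one missing follow-up carries the other; both missing propagates NA
  expect_equal(interval_expand(1, NA, 4), 96)
  expect_true(is.na(interval_expand(1, NA, NA)))
})

test_that("total societal cost matches hand-computed fixtures", {
  uc <- default_unit_costs()
  # wage 15.2: male, 30-39 band in the packaged table
  expect_equal(lookup_wage(uc, "M", 35), 15.2)

  p <- make_patient(arm = "control", age = 35, sex = "M", outpatient = 6)
  cb <- total_cost(p, uc)
  expect_equal(cb$outpatient, 6 * 40.02)
  expect_equal(cb$visit_absence, 6 * 3.3 * 15.2)
  expect_equal(cb$total, 6 * 40.02 + 6 * 3.3 * 15.2)
  expect_equal(cb$total_healthcare, 240.12)

  # all-zero patients cost nothing outside the telemonitoring arm and
  # exactly the rental inside it
  p0 <- make_patient(id = "z1", arm = "telephone")
  expect_equal(total_cost(p0, uc)$total, 0)
  ptm <- make_patient(id = "z2", arm = "telemonitoring")
  expect_equal(total_cost(ptm, uc)$total, 23.94)

  # a single emergency visit: 189 health care + 3.3 h absence
  pe <- make_patient(id = "e1", age = 35, sex = "M", emergency = 1)
  cbe <- total_cost(pe, uc)
  expect_equal(cbe$emergency, 189)
  expect_equal(cbe$total, 189 + 3.3 * 15.2)

  # telemonitoring contacts: provider cost + patient leisure time
  pt <- make_patient(id = "t1", arm = "telemonitoring", tm_nurse = 2,
                     tm_physician = 1)
  cbt <- total_cost(pt, uc)
  expect_equal(cbt$tm_contacts, 2 * 1.68 + 1 * 3.04)
  expect_equal(cbt$leisure_tm, 3 * 5 / 60 * 9.18)
})

test_that("unimputed missing cost fields are refused", {
  p <- make_patient()
  p$wpai_hours_missed_w24 <- NA_real_
  p$wpai_hours_missed_w12 <- NA_real_
  expect_error(total_cost(p), "imputation")
})

test_that("cost breakdowns are additive for random records", {
  pat <- random_patients(40, seed = 21)
  cb <- total_cost(pat)
  fields <- cost_fields()
  expect_equal(cb$total_healthcare,
               unname(rowSums(cb[, fields$healthcare])))
  expect_equal(cb$total_productivity,
               unname(rowSums(cb[, fields$productivity])))
  expect_equal(cb$total, cb$total_healthcare + cb$total_productivity)
  expect_true(all(as.matrix(cb[, unlist(fields)]) >= 0))
})

test_that("costs are linear in the unit rates", {
  pat <- random_patients(20, seed = 22)
  uc <- default_unit_costs()
  k <- 1.75
  scaled <- unclass(uc)
  for (key in c("emergency_visit", "outpatient_visit", "hospital_day",
                "surgical_hospital_day", "phone_call_nurse",
                "phone_call_physician", "nurse_salary_per_min",
                "physician_salary_per_min", "tm_rental_per_patient_month",
                "leisure_hour")) {
    scaled[[key]] <- scaled[[key]] * k
  }
  scaled$wage_table$M <- scaled$wage_table$M * k
  scaled$wage_table$F <- scaled$wage_table$F * k
  scaled$wage_table$min <- scaled$wage_table$min * k
  scaled$wage_table$max <- scaled$wage_table$max * k
  cb1 <- total_cost(pat, uc)
  cb2 <- total_cost(pat, validate_unit_costs(scaled))
  for (f in unlist(cost_fields())) {
    expect_equal(cb2[[f]], k * cb1[[f]], label = f)
  }
  # the packaged inflation multiplier scales everything the same way
  infl <- unclass(uc)
  infl$inflation_multiplier <- k
  cb3 <- total_cost(pat, validate_unit_costs(infl))
  expect_equal(cb3$total, k * cb1$total)
})

test_that("adding one unit of any resource never decreases the total", {
  pat <- random_patients(12, seed = 23)
  base <- total_cost(pat)$total
  for (col in c("emergency_visits", "outpatient_visits", "hospital_days",
                "surgical_days", "phone_nurse", "phone_physician")) {
    bumped <- pat
    bumped[[col]] <- bumped[[col]] + 1L
    expect_true(all(total_cost(bumped)$total >= base), label = col)
  }
  tm <- pat[pat$arm == "telemonitoring", ]
  base_tm <- total_cost(tm)$total
  for (col in c("tm_nurse", "tm_physician")) {
    bumped <- tm
    bumped[[col]] <- bumped[[col]] + 1L
    expect_true(all(total_cost(bumped)$total >= base_tm), label = col)
  }
})
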