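test_that("patient CSV round-trip preserves values and missingness", {
  pat <- generate_trial(seed = 3)
  expect_s3_class(pat, "cea_patients")
  expect_equal(nrow(pat), 63)
  expect_equal(as.vector(table(pat$arm)[cea_arms()]), rep(21L, 3))
  # default missingness: 3 telemonitoring patients lack week-24 reports
  expect_equal(sum(is.na(pat$eq5d_w24)), 3)

  path <- withr::local_tempfile(fileext = ".csv")
  write_patients(pat, path)
  back <- read_patients(path)
  expect_equal(as.data.frame(back), as.data.frame(pat))
})

test_that("empty and partially missing files are read faithfully", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_patients(make_patient()[0, ], path)
  expect_equal(nrow(read_patients(path)), 0)

  pat <- make_patient()
  pat$eq5d_w24 <- NA_real_
  write_patients(pat, path)
  back <- read_patients(path)
  expect_true(is.na(back$eq5d_w24))
  expect_false(is.na(back$eq5d_w0))
})

test_that("malformed input is rejected with a located error", {
  pat <- make_patient(id = "bad-1")
  pat$arm <- "armX"
  expect_error(validate_patients(pat), "bad-1.*arm.*unknown")

  pat <- make_patient(id = "bad-2")
  pat$wpai_work_impair_w12 <- 140
  expect_error(validate_patients(pat), "bad-2.*wpai_work_impair_w12")

  pat <- make_patient(id = "bad-3", arm = "control")
  pat$tm_nurse <- 2L
  expect_error(validate_patients(pat), "telemonitoring fields")

  pat <- make_patient(id = "bad-4")
  pat$outpatient_visits <- -1L
  expect_error(validate_patients(pat), "bad-4.*outpatient_visits")

  pat <- make_patient(id = "bad-5", employed = TRUE)
  pat$wpai_not_working_w12 <- TRUE
  pat$wpai_hours_worked_w12 <- 10
  expect_error(validate_patients(pat), "not_working")

  # non-numeric cell in a CSV names the row and column
  path <- withr::local_tempfile(fileext = ".csv")
  write_patients(make_patient(), path)
  raw <- utils::read.csv(path, colClasses = "character")
  raw$age_years <- "forty"
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  expect_error(read_patients(path), "age_years")
})

test_that("packaged unit costs reproduce every printed rate", {
  uc <- default_unit_costs()
  expect_equal(uc$emergency_visit, 189)
  expect_equal(uc$outpatient_visit, 40.02)
  expect_equal(uc$hospital_day, 310.17)
  expect_equal(uc$surgical_hospital_day, 378)
  expect_equal(uc$phone_call_nurse, 15)
  expect_equal(uc$phone_call_physician, 21.47)
  expect_equal(uc$tm_rental_per_patient_month, 3.99)
  expect_equal(uc$leisure_hour, 9.18)
  expect_equal(uc$visit_absence_hours, 3.3)
  expect_equal(uc$wage_table$min, 12.04)
  expect_equal(uc$wage_table$max, 25.23)
  # derived telemonitoring contact rates
  expect_equal(telemonitoring_contact_cost(uc$contact_minutes,
                                           uc$nurse_salary_per_min), 1.68)
  expect_equal(telemonitoring_contact_cost(uc$contact_minutes,
                                           uc$physician_salary_per_min),
               3.04)
})

test_that("unit cost config files merge with defaults and are validated", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("outpatient_visit: 45.0\ncall_minutes: 12", path)
  uc <- read_unit_costs(path)
  expect_equal(uc$outpatient_visit, 45)
  expect_equal(uc$call_minutes, 12)
  expect_equal(uc$emergency_visit, 189) # default retained

  writeLines("leisure_hour: 0", path)
  expect_error(read_unit_costs(path), "leisure_hour")

  writeLines("hospital_day: -5", path)
  expect_error(read_unit_costs(path), "hospital_day")

  # wage bounds are enforced
  bad <- unclass(default_unit_costs())
  bad$wage_table$M[1] <- 40
  expect_error(validate_unit_costs(bad), "min/max")

  # round trip
  write_unit_costs(default_unit_costs(), path)
  expect_equal(read_unit_costs(path), default_unit_costs())
})

test_that("wage lookup respects sex and age bands", {
  uc <- default_unit_costs()
  expect_equal(lookup_wage(uc, "F", 18), 12.04)
  expect_equal(lookup_wage(uc, "M", 45), uc$wage_table$M[3])
  expect_equal(lookup_wage(uc, c("M", "F"), c(65, 65)),
               c(uc$wage_table$M[5], uc$wage_table$F[5]))
  expect_error(lookup_wage(uc, "M", 10), "age")
})

test_that("analysis outputs are written as CSV plus manifest, deterministically", {
  pat <- make_mini_trial(n_per_arm = 8, seed = 5)
  res <- run_full_analysis(pat, m = 2, B = 40, seed = 2)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  files <- write_results(res, out1)
  expect_gte(length(files), 4)
  expect_true(file.exists(file.path(out1, "run_manifest.json")))
  manifest <- jsonlite::read_json(file.path(out1, "run_manifest.json"))
  expect_equal(manifest$seed, 2)
  expect_true(all(unlist(manifest$files) %in% list.files(out1)))

  # rerun with the same seed: numeric tables byte-identical
  res2 <- run_full_analysis(pat, m = 2, B = 40, seed = 2)
  write_results(res2, out2)
  for (f in setdiff(list.files(out1), "run_manifest.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }

  # metadata-only write for an empty contrast list
  out3 <- withr::local_tempdir()
  files3 <- write_results(list(contrasts = list(),
                               manifest = list(seed = 1)), out3)
  expect_identical(unname(files3), "run_manifest.json")
})
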