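# fixtures are built programmatically: a fully observed patient row with
# all-zero resource use and quiescent disease, which individual tests
# perturb

make_patient <- function(id = "p1", arm = "control", disease = "CD",
                         age = 40, sex = "M", employed = TRUE,
                         scores = c(3, 2, 1), eq5d = c(0.8, 0.9),
                         hours_missed = c(0, 0, 0),
                         hours_worked = c(35, 35, 35),
                         work_impair = c(0, 0, 0),
                         social_impair = c(0, 0, 0),
                         emergency = 0, outpatient = 0, hospital = 0,
                         surgical = 0, phone_nurse = 0,
                         phone_physician = 0, tm_nurse = 0,
                         tm_physician = 0,
                         tm_months = if (arm == "telemonitoring") 6 else 0,
                         calpro = c(200, 100)) {
  d <- data.frame(patient_id = id, arm = arm, disease = disease,
                  age_years = as.integer(age), sex = sex,
                  employed = employed, stringsAsFactors = FALSE)
  weeks <- c("w0", "w12", "w24")
  for (i in seq_along(weeks)) {
    w <- weeks[i]
    if (disease == "CD") {
      d[[paste0("hbi_", w)]] <- as.integer(scores[i])
      d[[paste0("sccai_", w)]] <- NA_integer_
      d[[paste0("pmayo_", w)]] <- NA_integer_
    } else {
      d[[paste0("hbi_", w)]] <- NA_integer_
      d[[paste0("sccai_", w)]] <- as.integer(scores[i])
      d[[paste0("pmayo_", w)]] <- as.integer(scores[i])
    }
  }
  d$eq5d_w0 <- eq5d[1]
  d$eq5d_w24 <- eq5d[2]
  for (i in seq_along(weeks)) {
    w <- weeks[i]
    d[[paste0("wpai_hours_missed_", w)]] <-
      if (employed) hours_missed[i] else 0
    d[[paste0("wpai_hours_worked_", w)]] <-
      if (employed) hours_worked[i] else 0
    d[[paste0("wpai_work_impair_", w)]] <- if (employed) work_impair[i] else 0
    d[[paste0("wpai_social_impair_", w)]] <- social_impair[i]
    d[[paste0("wpai_not_working_", w)]] <- !employed
  }
  d$emergency_visits <- as.integer(emergency)
  d$outpatient_visits <- as.integer(outpatient)
  d$hospital_days <- as.integer(hospital)
  d$surgical_days <- as.integer(surgical)
  d$phone_nurse <- as.integer(phone_nurse)
  d$phone_physician <- as.integer(phone_physician)
  d$tm_nurse <- as.integer(tm_nurse)
  d$tm_physician <- as.integer(tm_physician)
  d$tm_months <- tm_months
  d$calpro_w0 <- calpro[1]
  d$calpro_w24 <- calpro[2]
  d
}

make_cohort <- function(n, arm = "control", prefix = arm, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_patient(id = sprintf("%s-%02d", prefix, i), arm = arm, ...)
  }))
}

# a small complete three-arm trial with some per-patient variation
make_mini_trial <- function(n_per_arm = 6, seed = 99) {
  cfg <- default_trial_config()
  cfg$n_per_arm <- n_per_arm
  cfg$missingness$mechanism <- "none"
  generate_trial(cfg, seed = seed)
}

# random fully observed patient records for property tests
random_patients <- function(n, seed) {
  cfg <- default_trial_config()
  cfg$n_per_arm <- ceiling(n / 3)
  cfg$missingness$mechanism <- "none"
  pat <- generate_trial(cfg, seed = seed)
  pat[seq_len(n), ]
}

# exhaustive with-replacement resampling oracle for quadrant
# probabilities on tiny arms: every ordered index tuple is equally likely
enum_quadrants <- function(stats_a, stats_b, measure_col) {
  enum_means <- function(st) {
    n <- nrow(st)
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    list(cost = rowMeans(matrix(st$total[idx], nrow(idx))),
         eff = rowMeans(matrix(st[[measure_col]][idx], nrow(idx))))
  }
  a <- enum_means(stats_a)
  b <- enum_means(stats_b)
  dc <- outer(a$cost, b$cost, "-")
  de <- outer(a$eff, b$eff, "-")
  c(NE = mean(de > 0 & dc >= 0), SE = mean(de > 0 & dc < 0),
    SW = mean(de <= 0 & dc < 0), NW = mean(de <= 0 & dc >= 0))
}

# build a cea_draws data frame directly from given increments
draws_from <- function(delta_cost, delta_remission = 0, delta_qaly = 0) {
  structure(data.frame(imputation = 1L,
                       replicate = seq_along(delta_cost),
                       delta_cost = delta_cost,
                       delta_remission = rep_len(delta_remission,
                                                 length(delta_cost)),
                       delta_qaly = rep_len(delta_qaly,
                                            length(delta_cost))),
            class = c("cea_draws", "data.frame"))
}

# effect-summary table with given remission counts at w0/w24
remission_group <- function(n, n_rem_w0, n_rem_w24, arm = "telemonitoring") {
  pat <- make_cohort(n, arm = arm, prefix = paste0("rg", n_rem_w0))
  pat$hbi_w0 <- as.integer(c(rep(4, n_rem_w0), rep(5, n - n_rem_w0)))
  pat$hbi_w24 <- as.integer(c(rep(4, n_rem_w24), rep(5, n - n_rem_w24)))
  effect_summary(pat)
}
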