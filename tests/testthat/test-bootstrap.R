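test_that("the bootstrap emits m x B draws, reproducibly and extendably", {
  pat <- make_mini_trial(n_per_arm = 8, seed = 51)
  imp <- impute(pat, m = 3, seed = 4)
  d1 <- bootstrap_contrast(imp, "telemonitoring", "control", B = 50,
                           seed = 12)
  expect_s3_class(d1, "cea_draws")
  expect_equal(nrow(d1), 3 * 50)
  expect_true(all(is.finite(d1$delta_cost)))

  d2 <- bootstrap_contrast(imp, "telemonitoring", "control", B = 50,
                           seed = 12)
  expect_identical(d1, d2)

  # growing B extends the draw sequence without reshuffling earlier draws
  d3 <- bootstrap_contrast(imp, "telemonitoring", "control", B = 80,
                           seed = 12)
  expect_equal(d3[d3$replicate <= 50, ], d1, ignore_attr = TRUE)
  expect_error(bootstrap_contrast(imp, "telemonitoring", "control", B = 0),
               "B")
})

test_that("identical arms give draws centred at zero", {
  # two arms with the same cost/effect distribution
  a <- make_cohort(10, arm = "control", prefix = "a", outpatient = 3,
                   scores = c(5, 3, 2))
  b <- make_cohort(10, arm = "telephone", prefix = "b", outpatient = 3,
                   scores = c(5, 3, 2))
  a$outpatient_visits <- as.integer(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  b$outpatient_visits <- a$outpatient_visits
  d <- bootstrap_contrast(rbind(a, b), "control", "telephone", B = 2000,
                          seed = 3)
  expect_lt(abs(median(d$delta_cost)), 3 * sd(d$delta_cost) / sqrt(2000))
  expect_lt(abs(median(d$delta_remission)), 0.05)
})

test_that("draw means match the CLT oracle for known cohorts", {
  # deterministic per-patient costs/effects with known means
  a <- make_cohort(12, arm = "telemonitoring", prefix = "a")
  a$outpatient_visits <- as.integer(rep(c(2, 4, 6), 4)) # mean 4 visits
  a$eq5d_w24 <- rep(c(0.7, 0.9, 1.0), 4)
  b <- make_cohort(12, arm = "control", prefix = "b")
  b$outpatient_visits <- as.integer(rep(c(5, 6, 7), 4)) # mean 6
  b$eq5d_w24 <- rep(c(0.6, 0.8, 0.9), 4)
  uc <- default_unit_costs()
  st <- rbind(total_cost(a, uc), total_cost(b, uc))
  true_dc <- mean(st$total[1:12]) - mean(st$total[13:24])
  true_dq <- (mean(qaly(a$eq5d_w0, a$eq5d_w24)) -
                mean(qaly(b$eq5d_w0, b$eq5d_w24)))
  B <- 4000
  d <- bootstrap_contrast(rbind(a, b), "telemonitoring", "control", B = B,
                          seed = 8)
  se_dc <- sd(d$delta_cost) / sqrt(B)
  se_dq <- sd(d$delta_qaly) / sqrt(B)
  expect_lt(abs(mean(d$delta_cost) - true_dc), 3 * se_dc)
  expect_lt(abs(mean(d$delta_qaly) - true_dq), 3 * se_dq)
})

test_that("ICERs reproduce the printed ratio arithmetic", {
  expect_equal(round(icer(-211, 0.191)), -1105)
  expect_equal(icer(-135, 0.048), -2812.5)
  expect_equal(round(icer(-77, 0.143)), -538)
  expect_true(is.na(icer(100, 0)))
})

test_that("ICER summaries use percentiles of the defined draws", {
  d <- draws_from(delta_cost = rep(-500, 200),
                  delta_remission = rep(0.25, 200))
  s <- summarize_icer(d, "remission")
  expect_equal(s$median, -2000)
  expect_equal(s$ci_low, -2000) # identical draws collapse the interval
  expect_equal(s$ci_high, -2000)
  expect_equal(s$n_defined, 200)

  # draws with zero effect difference are excluded from the ratio
  d2 <- draws_from(delta_cost = rep(-500, 300),
                   delta_remission = c(rep(0.25, 150), rep(0, 150)))
  expect_equal(summarize_icer(d2, "remission")$n_defined, 150)
  expect_error(summarize_icer(d2, "remission", min_defined = 200),
               "bootstrap replicates")
})

test_that("quadrant probabilities sum to one and respect the tie rule", {
  d <- draws_from(delta_cost = c(-1, -1, 1, 0),
                  delta_remission = c(0.1, -0.1, 0.1, 0))
  q <- quadrant_probabilities(d, "remission")
  expect_equal(sum(q), 1)
  expect_equal(unname(q["SE"]), 0.25) # only the strict (-,+) draw
  expect_equal(unname(q["NW"]), 0.25) # boundary draw lands not-effective,
  # not-saving

  all_dom <- draws_from(delta_cost = rep(-5, 10),
                        delta_remission = rep(0.2, 10))
  expect_equal(unname(quadrant_probabilities(all_dom)["SE"]), 1)

  withr::with_seed(5, {
    centred <- draws_from(delta_cost = rnorm(20000),
                          delta_remission = rnorm(20000))
  })
  qc <- quadrant_probabilities(centred)
  expect_true(all(abs(qc - 0.25) < 3 * sqrt(0.25 * 0.75 / 20000)))
})

test_that("bootstrap quadrants match the exhaustive enumeration oracle", {
  # 4-patient arms, 2-3 distinct patient profiles each
  a <- make_cohort(4, arm = "telemonitoring", prefix = "a")
  a$outpatient_visits <- as.integer(c(1, 1, 6, 2))
  a$hbi_w24 <- as.integer(c(2, 2, 6, 2))
  b <- make_cohort(4, arm = "control", prefix = "b")
  b$outpatient_visits <- as.integer(c(3, 3, 3, 8))
  b$hbi_w24 <- as.integer(c(2, 6, 6, 6))
  st <- ceatrial:::.arm_stats(validate_patients(rbind(a, b)),
                              default_unit_costs(), 0.5)
  st$rem_incr <- st$rem24 - st$rem0
  exact <- enum_quadrants(st[1:4, ], st[5:8, ], "rem_incr")

  B <- 20000
  d <- bootstrap_contrast(rbind(a, b), "telemonitoring", "control", B = B,
                          seed = 31)
  q <- quadrant_probabilities(d, "remission")
  tol <- 3 * sqrt(pmax(exact * (1 - exact), 0.01) / B)
  expect_true(all(abs(q - exact) < tol),
              info = paste(round(q, 4), round(exact, 4), collapse = " "))
})

test_that("the CEAC is the net-monetary-benefit exceedance curve", {
  d <- draws_from(delta_cost = c(-10, -5, 5, 10),
                  delta_remission = c(0.1, -0.1, 0.1, -0.1))
  cv <- ceac(d, wtp_grid = c(0, 100, 1000), measure = "remission")
  expect_s3_class(cv, "cea_ceac")
  # lambda = 0 reduces to the probability of cost saving, exactly
  expect_equal(cv$probability[1], mean(d$delta_cost < 0))
  expect_error(ceac(d, wtp_grid = c(-5, 0)), ">= 0")

  # all effects positive: non-decreasing in lambda
  up <- draws_from(delta_cost = rnorm(500, 0, 50),
                   delta_remission = rep(0.2, 500))
  pv <- ceac(up, wtp_grid = seq(0, 5000, 250))$probability
  expect_true(all(diff(pv) >= 0))
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("the CEAC matches the closed-form bivariate-normal oracle", {
  muC <- -150; muE <- 0.04; sdC <- 400; sdE <- 0.2; r <- 0.3
  B <- 5000
  withr::with_seed(17, {
    zc <- rnorm(B); ze <- r * zc + sqrt(1 - r^2) * rnorm(B)
    d <- draws_from(delta_cost = muC + sdC * zc,
                    delta_remission = muE + sdE * ze)
  })
  grid <- seq(0, 20000, 1000)
  emp <- ceac(d, grid, "remission")$probability
  covCE <- r * sdC * sdE
  theo <- vapply(grid, function(l) {
    pnorm((l * muE - muC) / sqrt(l^2 * sdE^2 - 2 * l * covCE + sdC^2))
  }, numeric(1))
  se <- sqrt(pmax(theo * (1 - theo), 0.005) / B)
  expect_true(all(abs(emp - theo) < 3 * se))
})

test_that("with mostly harmful effect draws the CEAC decreases toward P(effect gain)", {
  withr::with_seed(23, {
    d <- draws_from(delta_cost = rnorm(20000, -200, 250),
                    delta_qaly = rnorm(20000, -0.018, 0.05))
  })
  p_gain <- mean(d$delta_qaly > 0) # ~ 36% of draws involve health gains
  expect_lt(p_gain, 0.5)
  cv <- ceac(d, wtp_grid = c(0, 5000, 20000, 1e7), measure = "qaly")
  expect_gt(cv$probability[1], p_gain) # cost saving is likely at lambda=0
  expect_lt(cv$probability[3], cv$probability[1]) # decreasing curve
  expect_equal(cv$probability[4], p_gain, tolerance = 0.02)
})

test_that("contrast analysis assembles pooled estimates and both measures", {
  pat <- make_mini_trial(n_per_arm = 8, seed = 52)
  imp <- impute(pat, m = 2, seed = 6)
  ct <- contrast_analysis(imp, "telemonitoring", "control", B = 200,
                          seed = 9)
  expect_s3_class(ct, "cea_contrast")
  expect_equal(nrow(ct$draws), 400)
  expect_equal(sum(ct$remission$quadrants), 1)
  expect_equal(sum(ct$qaly$quadrants), 1)
  expect_true(ct$remission$icer$ci_low <= ct$remission$icer$median &&
                ct$remission$icer$median <= ct$remission$icer$ci_high)
  expect_true(all(ct$remission$ceac$probability >= 0 &
                    ct$remission$ceac$probability <= 1))
  expect_output(print(ct), "median ICER")
})
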