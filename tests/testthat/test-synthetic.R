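test_that("subject generation is deterministic and respects bounds", {
  expect_identical(make_subject(1), make_subject(1))
  expect_false(identical(make_subject(1), make_subject(2)))
  cohort <- make_cohort(50, seed = 3)
  ages <- vapply(cohort, `[[`, numeric(1), "age")
  weights <- vapply(cohort, `[[`, numeric(1), "weight")
  expect_true(all(ages >= 7 & ages <= 13))
  expect_true(all(weights > 0))
  expect_identical(make_cohort(50, seed = 3), cohort)
})

test_that("cohort age distribution matches the truncated-normal target", {
  ages <- vapply(make_cohort(10000, seed = 11), `[[`, numeric(1), "age")
  # oracle: mean of N(9.7, 1.9) truncated to [7, 13], computed numerically
  a <- (7 - 9.7) / 1.9
  b <- (13 - 9.7) / 1.9
  expected <- 9.7 + 1.9 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mean(ages), expected, tolerance = 0.1 / expected)
})

test_that("default lab protocol has the published shape", {
  p <- make_lab_protocol()
  stations <- p[p$category %in% c("activity", "sedentary"), ]
  expect_equal(nrow(stations), 14)
  expect_equal(p$category[1], "rest")
  expect_equal(p$end[1] - p$start[1], 180)
  expect_equal(attr(p, "total_s"), 50 * 60)
  # at least one station per intensity class
  cls <- as.character(classify_met_intensity(stations$target_met))
  expect_true(all(c("SED", "LPA", "MPA", "VPA") %in% cls))
  # segments tile the session: ordered, non-overlapping, no gaps
  expect_equal(p$start[-1], p$end[-nrow(p)])
})

test_that("protocol durations are additive and validated", {
  p1 <- make_lab_protocol(n_activities = 1, rest_min = 3, transition_min = 1,
                          activity_min = 2)
  expect_equal(attr(p1, "total_s"), 6 * 60)
  expect_error(make_lab_protocol(rest_min = 0), "rest_min")
  expect_error(make_lab_protocol(n_activities = 0), "n_activities")
})

test_that("gas exchange tracks MET targets in the noiseless limit", {
  prot <- make_lab_protocol(n_activities = 1, activity_min = 5,
                            activity_mets = 3)
  s <- test_subject(weight = 30)
  b <- simulate_gas_exchange(s, prot, noiseless_params())
  act <- b$time_s > prot$start[3] & b$time_s <= prot$end[3]
  # 3 MET x 5 mL/kg/min x 30 kg = 450 mL/min on every activity breath
  expect_equal(unique(round(b$vo2_ml_min[act], 9)), 450)
  expect_true(all(diff(b$time_s) > 0))
  expect_error(simulate_gas_exchange(s, prot[0, ], noiseless_params()),
               "segment")
})

test_that("gas-exchange segment means are unbiased under noise", {
  prot <- make_lab_protocol(n_activities = 1, activity_min = 4,
                            activity_mets = 3.5)
  s <- test_subject(weight = 30)
  target <- 3.5 * 5 * 30
  means <- vapply(1:200, function(i) {
    p <- sim_params(vo2_noise_cv = 0.1, onkinetics_tau = 0, seed = i)
    b <- simulate_gas_exchange(s, prot, p)
    act <- b$time_s > prot$start[3]
    mean(b$vo2_ml_min[act])
  }, numeric(1))
  expect_lt(abs(mean(means) - target) / target, 0.02)
})

test_that("session VO2 integral matches programmed energy when noiseless", {
  prot <- make_lab_protocol()
  s <- test_subject(weight = 32)
  b <- simulate_gas_exchange(s, prot, noiseless_params(seed = 4))
  # step-function integral over the session (mL), breath intervals tile it
  bounds <- c(0, b$time_s)
  integral <- sum(b$vo2_ml_min * diff(bounds) / 60)
  expected <- sum(prot$target_met * 5 * 32 * (prot$end - prot$start) / 60)
  expect_equal(integral, expected, tolerance = 1e-10)
})

test_that("raising a segment's MET target raises simulated VO2 and ENMO", {
  s <- test_subject()
  mets <- c(1.2, 2, 3.5, 5, 7)
  vo2 <- vapply(mets, function(m) {
    prot <- make_lab_protocol(n_activities = 1, activity_min = 4,
                              activity_mets = m)
    p <- sim_params(vo2_noise_cv = 0.05, onkinetics_tau = 0, seed = 9)
    b <- simulate_gas_exchange(s, prot, p)
    mean(b$vo2_ml_min[b$time_s > prot$start[3]])
  }, numeric(1))
  expect_true(all(diff(vo2) > 0))
  enmo <- vapply(mets, function(m) {
    sched <- data.frame(start = 0, end = 120, wear = TRUE, target_met = m)
    a <- simulate_raw_accel(sched, sim_params(seed = 9), rate = 10)
    mean(compute_enmo(a, epoch = 60)$enmo_mg)
  }, numeric(1))
  expect_true(all(diff(enmo) >= 0))
})

test_that("raw acceleration respects rate, non-wear gravity, and targets", {
  sched <- data.frame(start = 0, end = 60, wear = TRUE, target_met = 4)
  a <- simulate_raw_accel(sched, sim_params(seed = 2), rate = 30)
  expect_equal(nrow(a), 1800)
  expect_identical(a, simulate_raw_accel(sched, sim_params(seed = 2),
                                         rate = 30))

  nw <- data.frame(start = 0, end = 60, wear = FALSE, target_met = NA)
  a0 <- simulate_raw_accel(nw, sim_params(accel_noise_floor = 0, seed = 3))
  expect_equal(sqrt(a0$x_g^2 + a0$y_g^2 + a0$z_g^2), rep(1, nrow(a0)))

  # programmed epoch ENMO is recovered on average (100 one-minute epochs)
  sched <- data.frame(start = 0, end = 6000, wear = TRUE, target_met = NA,
                      target_enmo_mg = 250)
  a <- simulate_raw_accel(sched, sim_params(seed = 4), rate = 10)
  e <- compute_enmo(a, epoch = 60)
  expect_equal(nrow(e), 100)
  expect_lt(abs(mean(e$enmo_mg) - 250), 5)
  expect_error(simulate_raw_accel(sched[0, ], sim_params()), "segment")
})

test_that("device summaries follow the bias/noise model", {
  tr <- list(subject_id = "S1", true_mvpa = 20, true_net_aee = 100)
  id <- simulate_device_summary(tr, sim_params(device_mvpa_sd = 0,
                                               device_aee_sd = 0))
  expect_equal(id$mvpa_min, 20)
  expect_equal(id$aee_kcal, 100)
  biased <- simulate_device_summary(tr, sim_params(device_mvpa_bias = 0.5,
                                                   device_mvpa_sd = 0))
  expect_equal(biased$mvpa_min, 30)
  # Monte-Carlo recovery: unbiased noisy device has mean bias ~ 0
  devs <- vapply(1:500, function(i) {
    simulate_device_summary(list(subject_id = paste0("S", i), true_mvpa = 20),
                            sim_params(device_mvpa_sd = 2, seed = 77))$mvpa_min
  }, numeric(1))
  se <- sd(devs - 20) / sqrt(500)
  expect_lt(abs(mean(devs - 20)), 3 * se)
})

test_that("free-living weeks carry coherent truth, logs, and structure", {
  s <- make_subject(5)
  wk <- simulate_free_living_week(s, sim_params(seed = 5), days = 7)
  expect_equal(nrow(wk$truth_daily), 7)
  expect_equal(sum(wk$truth_daily$true_mvpa), round(7 * 53.3))
  # every day has a non-wear bout of at least 90 minutes
  nonwear <- wk$schedule[!wk$schedule$wear & wk$schedule$kind == "nonwear", ]
  expect_equal(nrow(nonwear), 7)
  expect_true(all(nonwear$end - nonwear$start >= 90 * 60))
  expect_equal(nrow(wk$log), 21)
  expect_true(all(wk$log$kind %in% c("sleep", "nonwear")))
  # a week with no programmed activity has zero MVPA truth
  wk0 <- simulate_free_living_week(s, sim_params(seed = 5), days = 2,
                                   daily_mvpa_min = 0)
  expect_equal(wk0$truth_daily$true_mvpa, c(0, 0))
})
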