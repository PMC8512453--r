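test_that("breath aggregation is a time-weighted step-function mean", {
  b <- data.frame(time_s = c(20, 40, 60), vo2_ml_min = c(300, 300, 300))
  expect_equal(aggregate_breaths(b, epoch = 60)$vo2_rate, 300)

  b2 <- data.frame(time_s = c(30, 60), vo2_ml_min = c(200, 400))
  expect_equal(aggregate_breaths(b2, epoch = 60)$vo2_rate, 300)

  expect_error(aggregate_breaths(data.frame(time_s = c(2, 1),
                                            vo2_ml_min = c(1, 1))),
               "strictly increasing")
  expect_error(aggregate_breaths(b[0, ]), "at least one breath")

  # epochs with no coverage are missing, not zero
  late <- data.frame(time_s = c(130, 140), vo2_ml_min = c(100, 100))
  ep <- aggregate_breaths(late, epoch = 60, session_end = 180)
  expect_true(ep$missing[1])
  expect_true(is.na(ep$vo2_rate[1]))
})

test_that("breath aggregation agrees with a quadrature oracle", {
  set.seed(42)
  for (rep in 1:20) {
    times <- cumsum(runif(60, 0.5, 6))
    rates <- runif(60, 100, 1500)
    b <- data.frame(time_s = times, vo2_ml_min = rates)
    ep <- aggregate_breaths(b, epoch = 30,
                            session_end = times[length(times)])
    for (i in seq_len(nrow(ep))) {
      if (ep$missing[i]) next
      ora <- oracle_epoch_rate(times, rates, ep$epoch_start[i],
                               ep$epoch_start[i] + 30)
      expect_equal(ep$vo2_rate[i], ora, tolerance = 1e-9)
    }
  }
})

test_that("resting 1-MET is the mean over complete rest epochs", {
  prot <- make_lab_protocol()
  ep <- data.frame(epoch_start = c(0, 60, 120), vo2_rate = c(4.0, 4.4, NA),
                   missing = c(FALSE, FALSE, TRUE))
  r <- compute_resting_met(ep, prot, weight = 1)
  expect_equal(r$vo2_per_kg_1met, 4.2)
  expect_equal(r$n_epochs_used, 2)

  single <- data.frame(epoch_start = 0, vo2_rate = 5.0, missing = FALSE)
  expect_equal(compute_resting_met(single, prot, weight = 1)$vo2_per_kg_1met,
               5.0)
  norest <- prot[prot$category != "rest", ]
  expect_error(compute_resting_met(single, norest, weight = 1), "rest")
})

test_that("MET conversion follows its defining ratio", {
  ep <- data.frame(epoch_start = 0, vo2_rate = 300, missing = FALSE)
  resting <- structure(list(vo2_per_kg_1met = 5, n_epochs_used = 3),
                       class = "resting_rate")
  expect_equal(mets_from_vo2(ep, resting, weight = 30)$met, 2)
  # at the resting rate itself, MET is 1 by definition
  ep1 <- data.frame(epoch_start = 0, vo2_rate = 5 * 30, missing = FALSE)
  expect_equal(mets_from_vo2(ep1, resting, weight = 30)$met, 1)
  # doubling weight at fixed flow halves MET
  expect_equal(mets_from_vo2(ep, resting, weight = 60)$met, 1)
  expect_error(mets_from_vo2(ep, resting, weight = 0), "weight")
})

test_that("intensity classification partitions the MET line", {
  expect_equal(as.character(classify_met_intensity(c(4, 1.5, 6, 2.95))),
               c("MPA", "SED", "VPA", "LPA"))
  expect_equal(as.character(classify_met_intensity(c(0, 1.6, 3, 5.9, 20))),
               c("SED", "LPA", "MPA", "MPA", "VPA"))
  set.seed(1)
  m <- runif(500, 0, 12)
  cls <- classify_met_intensity(m)
  expect_false(any(is.na(cls)))  # exhaustive
  expect_error(classify_met_intensity(-0.1), "non-negative")
})

test_that("MVPA minutes count moderate+vigorous epochs, excluding transitions", {
  ep <- data.frame(
    epoch_start = 60 * (0:22),
    missing = FALSE,
    segment_category = c(rep("activity", 20), rep("transition", 3)),
    intensity = factor(c(rep("MPA", 20), rep("VPA", 3)),
                       levels = c("SED", "LPA", "MPA", "VPA"))
  )
  expect_equal(mvpa_minutes(ep), 20)
  ep$intensity <- factor("LPA", levels = levels(ep$intensity))
  expect_equal(mvpa_minutes(ep), 0)
  ep$intensity <- NULL
  expect_error(mvpa_minutes(ep), "classified")
})

test_that("oxygen-to-energy conversion is linear at 4.867 kcal/L", {
  expect_equal(vo2_to_kcal(1), 4.867)
  expect_equal(vo2_to_kcal(0), 0)
  expect_equal(vo2_to_kcal(2), 9.734)
  expect_error(vo2_to_kcal(-1), "non-negative")
  # forgetting the mL -> L conversion inflates energy by exactly 1000x
  expect_equal(vo2_to_kcal(500), 1000 * vo2_to_kcal(0.5))
})

test_that("gross active energy sums only activity-segment epochs", {
  ep <- data.frame(epoch_start = 60 * (0:2), vo2_rate = c(1000, 500, 800),
                   missing = FALSE,
                   segment_category = c("activity", "rest", "transition"))
  out <- gross_active_aee(ep)
  expect_equal(out$gross_aee, 4.867)
  expect_equal(out$active_minutes, 1)

  none <- ep
  none$segment_category <- "rest"
  expect_equal(gross_active_aee(none)$gross_aee, 0)

  const <- data.frame(epoch_start = 60 * (0:39), vo2_rate = 500,
                      missing = FALSE, segment_category = "activity")
  expect_equal(gross_active_aee(const)$gross_aee, 0.5 * 40 * 4.867)
})

test_that("Schofield BMR uses the sex- and band-specific coefficients", {
  expect_equal(schofield_bmr("male", age = 9, weight = 32),
               22.7 * 32 + 495)
  expect_equal(schofield_bmr("female", age = 9, weight = 32),
               22.5 * 32 + 499)
  expect_equal(schofield_bmr("male", age = 12, weight = 40),
               17.5 * 40 + 651)
  expect_equal(schofield_bmr("female", age = 10, weight = 35),
               12.2 * 35 + 746)
  expect_equal(schofield_bmr(test_subject(weight = 32)), 22.7 * 32 + 495)
  expect_error(schofield_bmr("male", age = 2, weight = 15), "age")
  expect_error(schofield_bmr("male", age = 9, weight = 0), "weight")
})

test_that("net AEE subtracts basal energy over active minutes", {
  expect_equal(net_aee(100, 1440, 40), 60)
  expect_equal(net_aee(100, 1440, 0), 100)
  expect_warning(out <- net_aee(10, 1440, 40), "negative")
  expect_equal(out, -30)
})

test_that("noiseless lab sessions round-trip programmed MVPA and net AEE", {
  p <- noiseless_params(seed = 21)
  prot <- make_lab_protocol()
  for (seed in c(1, 2)) {
    s <- make_subject(seed)
    truth <- lab_protocol_truth(prot, s, p)
    lab <- process_lab_session(simulate_gas_exchange(s, prot, p), prot, s)
    expect_equal(lab$mvpa, truth$true_mvpa)
    expect_lt(abs(lab$net_aee - truth$true_net_aee), 0.1)
    expect_equal(lab$resting$vo2_per_kg_1met, 5)
    expect_equal(lab$active_minutes, truth$active_minutes)
  }
})

test_that("halving the epoch leaves noiseless MVPA unchanged", {
  p <- noiseless_params(seed = 22)
  prot <- make_lab_protocol()
  s <- make_subject(3)
  b <- simulate_gas_exchange(s, prot, p)
  m60 <- process_lab_session(b, prot, s, epoch = 60)$mvpa
  m30 <- process_lab_session(b, prot, s, epoch = 30)$mvpa
  expect_equal(m30, m60)
})

test_that("epochs straddling segments go to the majority segment", {
  prot <- data.frame(label = c("a", "b"), start = c(0, 100), end = c(100, 200),
                     category = c("rest", "activity"), target_met = c(1, 4))
  ep <- data.frame(epoch_start = c(0, 60, 120), vo2_rate = 1,
                   missing = FALSE)
  out <- assign_epoch_segments(ep, prot, epoch = 60)
  # epoch [60, 120): 40 s in "a", 20 s in "b" -> majority "a"
  expect_equal(out$segment_label, c("a", "a", "b"))
  # exact tie goes to the earlier segment
  tie <- assign_epoch_segments(data.frame(epoch_start = 70, vo2_rate = 1,
                                          missing = FALSE),
                               prot, epoch = 60)
  expect_equal(tie$segment_label, "a")
})
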