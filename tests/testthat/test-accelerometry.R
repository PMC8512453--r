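test_that("ENMO truncates per sample before averaging", {
  up <- data.frame(time_s = 0:59, x_g = 0, y_g = 0, z_g = 1)
  expect_equal(compute_enmo(up, epoch = 60)$enmo_mg, 0)

  two <- data.frame(time_s = 0:59, x_g = 0, y_g = 0, z_g = 2)
  expect_equal(compute_enmo(two, epoch = 60)$enmo_mg, 1000)

  # half the samples at norm 0.5 g, half at 1.5 g: truncate-then-average
  # gives 250 mg, whereas averaging first would cancel to 0
  mix <- data.frame(time_s = 0:59, x_g = 0, y_g = 0,
                    z_g = rep(c(0.5, 1.5), 30))
  expect_equal(compute_enmo(mix, epoch = 60)$enmo_mg, 250)

  expect_error(compute_enmo(mix[0, ]), "empty")
})

test_that("ENMO is invariant under rigid rotations", {
  set.seed(7)
  sched <- data.frame(start = 0, end = 300, wear = TRUE, target_met = 4)
  a <- simulate_raw_accel(sched, sim_params(seed = 7), rate = 10)
  base <- compute_enmo(a, epoch = 60)$enmo_mg
  for (i in 1:5) {
    rot <- random_rotation()
    xyz <- as.matrix(a[, c("x_g", "y_g", "z_g")]) %*% t(rot)
    ar <- data.frame(time_s = a$time_s, x_g = xyz[, 1], y_g = xyz[, 2],
                     z_g = xyz[, 3])
    expect_equal(compute_enmo(ar, epoch = 60)$enmo_mg, base,
                 tolerance = 1e-12)
  }
})

test_that("epochs with no samples are flagged missing", {
  gap <- data.frame(time_s = c(0:59, 180:239), x_g = 0, y_g = 0, z_g = 1.2)
  e <- compute_enmo(gap, epoch = 60)
  expect_equal(e$missing, c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(is.na(e$enmo_mg[e$missing])))
})

test_that("cut-point sets validate and classify with left-closed bands", {
  cuts <- cut_points()
  expect_equal(cuts$lpa_threshold, 35.6)
  expect_equal(cuts$mpa_threshold, 201.4)
  expect_equal(cuts$vpa_threshold, 707.0)
  expect_error(cut_points("nope"), "unknown")
  expect_error(cut_points("custom", lpa_threshold = 50, mpa_threshold = 40,
                          vpa_threshold = 700), "lpa < mpa < vpa")

  rec <- data.frame(minute_start = 60 * (0:4),
                    enmo_mg = c(0, 35.6, 201.4, 707 - 1e-9, 707))
  out <- classify_enmo(rec, cuts)
  expect_equal(as.character(out$intensity),
               c("SED", "LPA", "MPA", "MPA", "VPA"))
})

test_that("autocalibration recovers simulated offset and gain", {
  set.seed(11)
  rate <- 30
  true_off <- c(0.05, 0, -0.02)
  true_gain <- c(1.02, 1, 0.97)
  # 12 stationary orientations, 60 s each, small sensor noise
  parts <- lapply(1:12, function(i) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    n <- rate * 60
    truth <- matrix(u, n, 3, byrow = TRUE) + matrix(rnorm(3 * n, 0, 0.003),
                                                    n, 3)
    raw <- sweep(sweep(truth, 2, true_off, `-`), 2, true_gain, `/`)
    data.frame(time_s = (i - 1) * 60 + (seq_len(n) - 1) / rate,
               x_g = raw[, 1], y_g = raw[, 2], z_g = raw[, 3])
  })
  samples <- do.call(rbind, parts)
  model <- autocalibrate(samples, rate = rate)
  expect_true(model$converged)
  expect_lt(max(abs(model$offset - true_off)), 0.005)
  expect_lt(max(abs(model$gain - true_gain)), 0.005)

  # applying the model brings stationary norms to 1 g
  cal <- apply_calibration(samples, model)
  nrm <- sqrt(cal$x_g^2 + cal$y_g^2 + cal$z_g^2)
  expect_lt(abs(mean(nrm) - 1), 0.002)
})

test_that("calibration degenerates safely", {
  rate <- 30
  n <- rate * 720
  flat <- data.frame(time_s = (seq_len(n) - 1) / rate,
                     x_g = 0.01, y_g = 0.02, z_g = 0.99)
  model <- autocalibrate(flat, rate = rate)
  expect_false(model$converged)
  expect_equal(model$offset, c(0, 0, 0))
  expect_equal(model$gain, c(1, 1, 1))

  # already-calibrated multi-orientation data: identity is a fixed point
  set.seed(12)
  parts <- lapply(1:6, function(i) {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    k <- rate * 120
    m <- matrix(u, k, 3, byrow = TRUE) + matrix(rnorm(3 * k, 0, 0.002), k, 3)
    data.frame(time_s = (i - 1) * 120 + (seq_len(k) - 1) / rate,
               x_g = m[, 1], y_g = m[, 2], z_g = m[, 3])
  })
  model2 <- autocalibrate(do.call(rbind, parts), rate = rate)
  expect_true(model2$converged)
  expect_lt(max(abs(model2$offset)), 0.003)
  expect_lt(max(abs(model2$gain - 1)), 0.003)

  expect_error(autocalibrate(flat[1:100, ], rate = rate), "10 minutes")
})

test_that("non-wear detection matches its published worked examples", {
  # >= 90 min of zeros is non-wear in full
  x <- c(rep(5, 10), rep(0, 100), rep(5, 10))
  w <- detect_nonwear(x)
  expect_equal(sum(!w), 100)
  expect_true(all(w[1:10]))

  # 89 zeros bounded by activity stay wear
  x89 <- c(rep(5, 10), rep(0, 89), rep(5, 10))
  expect_true(all(detect_nonwear(x89)))

  # a 2-min spike flanked by >= 30-min zero runs is absorbed
  xs <- c(rep(0, 60), rep(5, 2), rep(0, 60))
  expect_equal(sum(!detect_nonwear(xs)), 122)

  # a 3-min spike breaks the span: both halves < 90 min
  xl <- c(rep(0, 60), rep(5, 3), rep(0, 60))
  expect_true(all(detect_nonwear(xl)))

  # series shorter than the window is all wear
  expect_true(all(detect_nonwear(rep(0, 50))))
})

test_that("non-wear detection agrees with the positional oracle", {
  set.seed(99)
  for (i in 1:200) {
    x <- random_minute_sequence(300)
    expect_identical(detect_nonwear(x), oracle_nonwear(x))
  }
})

test_that("log exclusion composes monotonically with wear detection", {
  rec <- data.frame(minute_start = 60 * (0:1439),
                    enmo_mg = 50, wear = TRUE)
  d0 <- as.Date("2021-04-05")
  same <- apply_logs(rec, NULL, d0)
  expect_false(any(same$excluded_by_log))

  full <- data.frame(date = d0, start_hms = "00:00:00", end_hms = "24:00:00",
                     kind = "sleep")
  all_out <- apply_logs(rec, full, d0)
  expect_true(all(all_out$excluded_by_log))

  half_hour <- data.frame(date = d0, start_hms = "10:00:00",
                          end_hms = "10:30:00", kind = "nonwear")
  part <- apply_logs(rec, half_hour, d0)
  expect_equal(sum(part$excluded_by_log), 30)

  bad <- data.frame(date = d0, start_hms = "10:00:00", end_hms = "09:00:00",
                    kind = "nonwear")
  expect_error(apply_logs(rec, bad, d0), "end after start")

  # adding intervals never increases wear minutes
  rec2 <- classify_enmo(rec, cut_points())
  base <- daily_mvpa(apply_logs(rec2, NULL, d0))$daily$wear_minutes
  less <- daily_mvpa(apply_logs(rec2, half_hour, d0))$daily$wear_minutes
  expect_true(all(less <= base))
})

test_that("daily aggregation averages retained days only", {
  mk_day <- function(day, mvpa) {
    n <- 1440
    data.frame(minute_start = day * 86400 + 60 * (0:(n - 1)),
               intensity = factor(c(rep("MPA", mvpa),
                                    rep("SED", n - mvpa)),
                                  levels = c("SED", "LPA", "MPA", "VPA")),
               wear = TRUE, excluded_by_log = FALSE)
  }
  rec <- rbind(mk_day(0, 40), mk_day(1, 60))
  out <- daily_mvpa(rec)
  expect_equal(out$daily$mvpa, c(40, 60))
  expect_equal(out$mean_mvpa, 50)

  # a short-wear day is dropped from the mean
  short <- mk_day(2, 100)[1:300, ]
  out2 <- daily_mvpa(rbind(rec, short))
  expect_equal(out2$mean_mvpa, 50)
  expect_equal(sum(out2$daily$retained), 2)

  none <- mk_day(0, 10)
  none$wear <- FALSE
  expect_error(daily_mvpa(none), "minimum wear")
})
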