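# Independent reference implementations used as oracles.

# Positional (minute-by-minute) reference for the non-wear rule: a span of
# zeros >= `window` min, where interruptions of <= `spike_tolerance`
# consecutive non-zero minutes are allowed when the adjacent zero runs on
# both sides are >= `flank` minutes. Written as a forward scan over
# positions with explicit consecutive-zero bookkeeping, independently of
# the package's run-length-encoding implementation.
oracle_nonwear <- function(x, window = 90, spike_tolerance = 2, flank = 30,
                           zero_threshold = 1) {
  n <- length(x)
  zero <- ifelse(is.na(x), TRUE, x < zero_threshold)
  nonwear <- rep(FALSE, n)
  if (n < window) return(!nonwear)
  zl <- integer(n)  # consecutive zeros ending at k
  zr <- integer(n)  # consecutive zeros starting at k
  for (k in seq_len(n)) {
    zl[k] <- if (zero[k]) (if (k > 1) zl[k - 1] else 0L) + 1L else 0L
  }
  for (k in rev(seq_len(n))) {
    zr[k] <- if (zero[k]) (if (k < n) zr[k + 1] else 0L) + 1L else 0L
  }
  i <- 1L
  while (i <= n) {
    if (!zero[i] || (i > 1 && zero[i - 1])) {
      i <- i + 1L
      next
    }
    j <- i + zr[i] - 1L  # end of the initial zero run
    repeat {
      s <- j + 1L
      if (s > n || zero[s]) break
      e <- s
      while (e < n && !zero[e + 1L]) e <- e + 1L
      spike_ok <- (e - s + 1L) <= spike_tolerance &&
        e < n && zl[j] >= flank && zr[e + 1L] >= flank
      if (!spike_ok) break
      j <- e + zr[e + 1L]
    }
    if (j - i + 1L >= window) nonwear[i:j] <- TRUE
    i <- j + 1L
  }
  !nonwear
}

# Random per-minute activity sequences with realistic run structure:
# long-ish zero runs interleaved with short bursts of movement.
random_minute_sequence <- function(n = 300) {
  x <- numeric(0)
  while (length(x) < n) {
    zl <- rgeom(1, 1 / 35) + 1
    sl <- rgeom(1, 1 / 2.5) + 1
    x <- c(x, rep(0, zl), runif(sl, 2, 200))
  }
  x[seq_len(n)]
}

# Quadrature oracle for the breath step function: each breath's rate holds
# over the interval since the previous breath. Integrates exactly by
# splitting the window at every breath time with a plain loop.
oracle_epoch_rate <- function(times, rates, lo, hi) {
  hi <- min(hi, times[length(times)])
  if (hi <= lo) return(NA_real_)
  pts <- sort(unique(c(lo, hi, times[times > lo & times < hi])))
  total <- 0
  for (k in seq_len(length(pts) - 1)) {
    a <- pts[k]
    b <- pts[k + 1]
    i <- which(times >= b - 1e-12)[1]  # rate in force on (a, b]
    total <- total + rates[i] * (b - a)
  }
  total / (hi - lo)
}

# Random rotation matrix (det +1) via QR.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Minimal subject for unit tests with controllable weight.
test_subject <- function(weight = 30, sex = "male", age = 9, height = 135,
                         id = "T1") {
  structure(list(subject_id = id, sex = sex, age = age, height = height,
                 weight = weight), class = "subject_profile")
}

# Noise-free simulation parameters for exact round trips; `...` overrides.
noiseless_params <- function(seed = 1, ...) {
  args <- list(vo2_noise_cv = 0, onkinetics_tau = 0, accel_enmo_cv = 0,
               accel_noise_floor = 0, device_mvpa_sd = 0, device_aee_sd = 0,
               seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}
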