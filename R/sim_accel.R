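#' Simulate raw tri-axial wrist acceleration over a schedule
#'
#' Produces fixed-rate samples in g. During worn segments the per-sample
#' vector magnitude is `1 + e/1000` g where `e` (mg) is the segment's
#' target ENMO (the affine MET map in [sim_params()], or a `target_enmo_mg`
#' column if the schedule provides one) times a mean-1 lognormal factor of
#' CV `params$accel_enmo_cv`; directions jitter around a per-segment
#' orientation. The per-sample ENMO thus equals the movement magnitude
#' exactly, and epoch means converge on the target. During non-wear the
#' signal is a fixed unit-norm gravity vector plus uniform per-axis sensor
#' noise bounded by `params$accel_noise_floor` mg.
#'
#' @param schedule `data.frame` with columns `start`, `end` (seconds),
#'   `wear` (logical) and `target_met` (may be `NA` for non-wear); an
#'   optional `target_enmo_mg` column overrides the MET map.
#' @param params A [sim_params()] object.
#' @param rate Sampling rate in Hz (default 30).
#' @return A `data.frame` with columns `time_s`, `x_g`, `y_g`, `z_g`, one
#'   row per sample, with the rate stored in a `rate_hz` attribute.
#' @export
#' @examples
#' sched <- data.frame(start = 0, end = 60, wear = TRUE, target_met = 4)
#' a <- simulate_raw_accel(sched, sim_params(seed = 2), rate = 30)
#' nrow(a)  # 1800
simulate_raw_accel <- function(schedule, params = sim_params(), rate = 30) {
  if (is.null(schedule) || nrow(schedule) == 0) {
    stop("`schedule` must contain at least one segment", call. = FALSE)
  }
  stop_if_not_scalar_number(rate, "rate", min = 0, closed_min = FALSE)
  stopifnot(all(c("start", "end", "wear") %in% names(schedule)))
  if (any(schedule$end <= schedule$start)) {
    stop("schedule segments must have end > start", call. = FALSE)
  }

  target_e <- if ("target_enmo_mg" %in% names(schedule)) {
    ifelse(schedule$wear, schedule$target_enmo_mg, 0)
  } else {
    ifelse(schedule$wear, met_to_enmo(schedule$target_met, params), 0)
  }

  key <- paste0("accel:", round(schedule$start[1]), ":",
                round(schedule$end[nrow(schedule)]))
  with_seed(split_seed(params$seed, key), {
    parts <- vector("list", nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      n <- round((schedule$end[i] - schedule$start[i]) * rate)
      if (n <= 0) next
      t <- schedule$start[i] + (seq_len(n) - 1) / rate
      u <- random_unit_vector()
      if (schedule$wear[i]) {
        e_g <- target_e[i] / 1000 * mult_noise(n, params$accel_enmo_cv)
        dir <- jitter_directions(u, n, sd = 0.15)
        xyz <- dir * (1 + e_g)
      } else {
        noise <- matrix(runif(3 * n, -params$accel_noise_floor,
                              params$accel_noise_floor) / 1000, ncol = 3)
        xyz <- matrix(u, nrow = n, ncol = 3, byrow = TRUE) + noise
      }
      parts[[i]] <- data.frame(time_s = t, x_g = xyz[, 1], y_g = xyz[, 2],
                               z_g = xyz[, 3])
    }
    out <- do.call(rbind, parts)
    attr(out, "rate_hz") <- rate
    out
  })
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# n unit vectors scattered around u with per-axis Gaussian jitter.
jitter_directions <- function(u, n, sd = 0.15) {
  m <- matrix(u, nrow = n, ncol = 3, byrow = TRUE) +
    matrix(rnorm(3 * n, 0, sd), ncol = 3)
  m / sqrt(rowSums(m^2))
}
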