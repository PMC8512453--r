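#' Simulate breath-by-breath gas exchange over a lab protocol
#'
#' Generates a breath record series whose expected oxygen-uptake rate tracks
#' each segment's MET target times the subject's resting VO2
#' (`params$resting_vo2_per_kg * weight`), with first-order on-kinetics of
#' time constant `params$onkinetics_tau` across segment changes and
#' multiplicative lognormal noise of coefficient of variation
#' `params$vo2_noise_cv` (mean exactly 1, so segment means are unbiased).
#'
#' Each breath reports the average uptake rate over its own interval; breath
#' spacing is gamma-distributed with mean `params$breath_interval_mean` and
#' restarts at each segment boundary (the final breath of a segment is
#' truncated at the boundary), so a breath never spans two segments. With
#' noise and kinetics switched off the recorded rates are therefore exactly
#' the programmed step function, and downstream epoch processing recovers
#' segment targets to machine precision.
#'
#' @param subject A [make_subject()] profile.
#' @param protocol A [make_lab_protocol()] segment table.
#' @param params A [sim_params()] object.
#' @return A `data.frame` with columns `time_s` (breath interval end,
#'   strictly increasing), `vo2_ml_min`, `vco2_ml_min`. VCO2 is carried at
#'   a fixed respiratory exchange ratio of 0.88 and is unused downstream.
#' @export
#' @examples
#' s <- make_subject(1)
#' p <- make_lab_protocol()
#' b <- simulate_gas_exchange(s, p, sim_params(seed = 1))
#' head(b)
simulate_gas_exchange <- function(subject, protocol, params = sim_params()) {
  validate_subject(subject)
  if (is.null(protocol) || nrow(protocol) == 0) {
    stop("`protocol` must contain at least one segment", call. = FALSE)
  }
  validate_protocol(protocol)
  tau <- params$onkinetics_tau
  rest_rate <- params$resting_vo2_per_kg * subject$weight  # mL/min at 1 MET

  with_seed(split_seed(params$seed, paste0("gas:", subject$subject_id)), {
    m_state <- protocol$target_met[1]  # start at steady state of segment 1
    times <- numeric(0)
    vo2 <- numeric(0)
    for (i in seq_len(nrow(protocol))) {
      seg <- protocol[i, ]
      bounds <- breath_boundaries(seg$start, seg$end,
                                  params$breath_interval_mean)
      a <- bounds[-length(bounds)]
      b <- bounds[-1]
      target <- seg$target_met
      if (tau <= 0) {
        met_mean <- rep(target, length(a))
        m_state <- target
      } else {
        # M(t) = target + (m0 - target) exp(-(t - t0)/tau); interval mean
        # over (a, b] has the closed form below.
        m0 <- m_state
        ea <- exp(-(a - seg$start) / tau)
        eb <- exp(-(b - seg$start) / tau)
        met_mean <- target + (m0 - target) * tau * (ea - eb) / (b - a)
        m_state <- target + (m0 - target) * exp(-(seg$end - seg$start) / tau)
      }
      rate <- met_mean * rest_rate * mult_noise(length(a), params$vo2_noise_cv)
      times <- c(times, b)
      vo2 <- c(vo2, rate)
    }
    data.frame(time_s = times, vo2_ml_min = vo2, vco2_ml_min = 0.88 * vo2)
  })
}

# Breath interval boundaries covering [start, end]: gamma-distributed
# spacings (shape 16, CV 25%) around the mean, last interval truncated at
# the segment end so intervals tile the segment exactly.
breath_boundaries <- function(start, end, mean_interval) {
  dur <- end - start
  n_guess <- ceiling(dur / mean_interval * 1.8) + 10
  gaps <- rgamma(n_guess, shape = 16, scale = mean_interval / 16)
  while (sum(gaps) < dur) {
    gaps <- c(gaps, rgamma(n_guess, shape = 16, scale = mean_interval / 16))
  }
  b <- start + cumsum(gaps)
  b <- b[b < end - 1e-9]
  c(start, b, end)
}
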