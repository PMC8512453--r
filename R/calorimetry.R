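#' @rdname vo2_to_kcal
#' @format `KCAL_PER_L_O2` is the caloric equivalent constant, 4.867 kcal
#'   per liter of oxygen.
#' @export
KCAL_PER_L_O2 <- 4.867

#' Aggregate breath records into fixed epochs
#'
#' Treats the breath series as a step function: each breath's rate applies
#' over the interval since the previous breath (the first interval starts
#' at `session_start`). A breath's interval extends at most `max_gap`
#' seconds back, so stretches with no breaths (mask off, signal dropout)
#' are uncovered rather than back-filled. Each epoch's rate is the
#' time-weighted mean of the step function over the part of the epoch the
#' series covers; epochs with no coverage are flagged missing (`NA`),
#' never zero.
#'
#' @param series `data.frame` with `time_s` (strictly increasing) and
#'   `vo2_ml_min`.
#' @param epoch Epoch length in seconds (default 60).
#' @param session_start Start of the session (s); epochs tile from here.
#' @param session_end End of the session (s); defaults to the last breath.
#' @param max_gap Longest interval (s) a single breath may represent;
#'   default 30, an order of magnitude above a child's breath spacing.
#' @return A `data.frame` with `epoch_start`, `vo2_rate` (mL/min, `NA` if
#'   missing), `covered_s`, and `missing`.
#' @export
#' @examples
#' b <- data.frame(time_s = c(30, 60), vo2_ml_min = c(200, 400))
#' aggregate_breaths(b, epoch = 60)$vo2_rate  # 300
aggregate_breaths <- function(series, epoch = 60, session_start = 0,
                              session_end = NULL, max_gap = 30) {
  if (is.null(series) || nrow(series) == 0) {
    stop("`series` must contain at least one breath", call. = FALSE)
  }
  stop_if_not_scalar_number(epoch, "epoch", min = 0, closed_min = FALSE)
  t <- series$time_s
  if (is.unsorted(t, strictly = TRUE)) {
    stop("breath times must be strictly increasing", call. = FALSE)
  }
  if (t[1] <= session_start) {
    stop("first breath must fall after `session_start`", call. = FALSE)
  }
  if (is.null(session_end)) session_end <- t[length(t)]
  v <- series$vo2_ml_min
  n <- length(t)

  # Alternating uncovered/covered segments: breath i covers
  # (max(t[i-1], t[i] - max_gap), t[i]].
  prev <- c(session_start, t[-n])
  a <- pmax(prev, t - max_gap)
  bp <- c(session_start, as.vector(rbind(a, t)))  # 2n + 1 breakpoints
  seg_val <- as.vector(rbind(0, v))               # odd segs uncovered
  seg_cov <- as.vector(rbind(0, 1))
  cum_i <- c(0, cumsum(seg_val * diff(bp)))
  cum_c <- c(0, cumsum(seg_cov * diff(bp)))
  eval_cum <- function(x, cum, val) {
    x <- pmin(pmax(x, bp[1]), bp[length(bp)])
    i <- findInterval(x, bp, rightmost.closed = TRUE)
    i <- pmin(i, length(val))
    cum[i] + val[i] * (x - bp[i])
  }

  n_ep <- ceiling((session_end - session_start) / epoch - 1e-9)
  starts <- session_start + (seq_len(max(1, n_ep)) - 1) * epoch
  ends <- pmin(starts + epoch, session_end)
  covered <- eval_cum(ends, cum_c, seg_cov) - eval_cum(starts, cum_c, seg_cov)
  integral <- eval_cum(ends, cum_i, seg_val) -
    eval_cum(starts, cum_i, seg_val)
  missing <- covered <= 1e-9
  rate <- ifelse(missing, NA_real_, integral / pmax(covered, 1e-12))
  data.frame(epoch_start = starts, vo2_rate = rate, covered_s = covered,
             missing = missing)
}

#' Assign epochs to protocol segments
#'
#' Each epoch is assigned to the segment covering the majority of it; ties
#' go to the earlier segment. Epochs not overlapping any segment get `NA`.
#'
#' @param epochs Output of [aggregate_breaths()].
#' @param protocol A [make_lab_protocol()] segment table.
#' @param epoch Epoch length in seconds.
#' @return `epochs` with added `segment_category` and `segment_label`.
#' @export
assign_epoch_segments <- function(epochs, protocol, epoch = 60) {
  validate_protocol(protocol)
  starts <- epochs$epoch_start
  n_seg <- nrow(protocol)
  overlap <- matrix(0, nrow = length(starts), ncol = n_seg)
  for (j in seq_len(n_seg)) {
    overlap[, j] <- pmax(0, pmin(starts + epoch, protocol$end[j]) -
                           pmax(starts, protocol$start[j]))
  }
  best <- apply(overlap, 1, function(r) if (max(r) > 0) which.max(r) else NA)
  epochs$segment_category <- protocol$category[best]
  epochs$segment_label <- protocol$label[best]
  epochs
}

#' Individualized resting metabolic rate (1-MET baseline)
#'
#' Averages VO2 per kg over the epochs lying fully inside the protocol's
#' rest segment; this measured resting rate defines 1 MET for the subject,
#' rather than the adult 3.5 mL/kg/min convention.
#'
#' @param epochs Output of [aggregate_breaths()].
#' @param protocol A protocol containing a `rest` segment.
#' @param weight Subject body weight in kg.
#' @param epoch Epoch length in seconds.
#' @return A list of class `resting_rate` with `vo2_per_kg_1met`
#'   (mL/kg/min) and `n_epochs_used`.
#' @export
compute_resting_met <- function(epochs, protocol, weight, epoch = 60) {
  stop_if_not_scalar_number(weight, "weight", min = 0, closed_min = FALSE)
  rest <- protocol[protocol$category == "rest", , drop = FALSE]
  if (nrow(rest) == 0) stop("protocol has no rest segment", call. = FALSE)
  inside <- epochs$epoch_start >= rest$start[1] - 1e-9 &
    epochs$epoch_start + epoch <= rest$end[1] + 1e-9 & !epochs$missing
  if (!any(inside)) {
    stop("no complete epochs inside the rest segment", call. = FALSE)
  }
  v <- mean(epochs$vo2_rate[inside]) / weight
  structure(list(vo2_per_kg_1met = v, n_epochs_used = sum(inside)),
            class = "resting_rate")
}

#' Convert epoch VO2 rates to METs
#'
#' `met = (vo2_rate / weight) / vo2_per_kg_1met`, the measured rate
#' expressed as a multiple of the subject's own resting rate.
#'
#' @param epochs Output of [aggregate_breaths()].
#' @param resting A [compute_resting_met()] result.
#' @param weight Body weight in kg (> 0).
#' @return `epochs` with added `vo2_per_kg` and `met` columns.
#' @export
mets_from_vo2 <- function(epochs, resting, weight) {
  stop_if_not_scalar_number(weight, "weight", min = 0, closed_min = FALSE)
  if (!inherits(resting, "resting_rate") || resting$vo2_per_kg_1met <= 0) {
    stop("`resting` must be a resting_rate with positive 1-MET rate",
         call. = FALSE)
  }
  epochs$vo2_per_kg <- epochs$vo2_rate / weight
  epochs$met <- epochs$vo2_per_kg / resting$vo2_per_kg_1met
  epochs
}

#' Classify METs into intensity classes
#'
#' Uses the study bands with half-open closure of the printed gaps:
#' SED for `met <= 1.5`, LPA for `1.5 < met < 3`, MPA for `3 <= met < 6`,
#' VPA for `met >= 6`. The printed anchors 1.5, 3.0, 6.0 are preserved and
#' every non-negative MET maps to exactly one class.
#'
#' @param met Numeric vector of non-negative METs (`NA` allowed).
#' @return Factor with levels `SED`, `LPA`, `MPA`, `VPA`.
#' @export
#' @examples
#' classify_met_intensity(c(1.5, 2.95, 4, 6))
classify_met_intensity <- function(met) {
  if (any(met < 0, na.rm = TRUE)) {
    stop("METs must be non-negative", call. = FALSE)
  }
  cls <- ifelse(met <= 1.5, "SED",
                ifelse(met < 3, "LPA",
                       ifelse(met < 6, "MPA", "VPA")))
  factor(cls, levels = c("SED", "LPA", "MPA", "VPA"))
}

#' MVPA minutes from classified epochs
#'
#' Counts epochs classified moderate or vigorous, excluding transition
#' epochs and missing epochs, times the epoch length in minutes.
#'
#' @param epochs Epochs with `met`-derived `intensity` and
#'   `segment_category` columns.
#' @param epoch Epoch length in seconds.
#' @return MVPA time in minutes.
#' @export
mvpa_minutes <- function(epochs, epoch = 60) {
  if (is.null(epochs$intensity) || any(is.na(epochs$intensity) &
                                       !epochs$missing)) {
    stop("epochs must be classified before counting MVPA", call. = FALSE)
  }
  keep <- !epochs$missing & epochs$segment_category != "transition" &
    !is.na(epochs$segment_category)
  sum(epochs$intensity[keep] %in% c("MPA", "VPA")) * epoch / 60
}

#' Caloric equivalent of oxygen uptake
#'
#' Fixed conversion of 4.867 kcal per liter of oxygen consumed.
#'
#' @param vo2_liters Oxygen volume in liters (>= 0).
#' @return Energy in kcal.
#' @export
#' @examples
#' vo2_to_kcal(1)  # 4.867
vo2_to_kcal <- function(vo2_liters) {
  if (any(vo2_liters < 0, na.rm = TRUE)) {
    stop("oxygen volume must be non-negative", call. = FALSE)
  }
  KCAL_PER_L_O2 * vo2_liters
}

#' Gross active energy expenditure
#'
#' Sums per-epoch kilocalories over epochs assigned to `activity` segments
#' only (rest, sedentary stations, and transitions are removed). Per-epoch
#' kcal is the VO2 rate converted to L/min, times 4.867 kcal/L, times the
#' epoch length in minutes. Missing epochs contribute neither energy nor
#' active time.
#'
#' @param epochs Epochs with `vo2_rate` and `segment_category`.
#' @param epoch Epoch length in seconds.
#' @return A list with `gross_aee` (kcal) and `active_minutes`.
#' @export
gross_active_aee <- function(epochs, epoch = 60) {
  if (is.null(epochs$segment_category)) {
    stop("epochs must be aligned to protocol segments first", call. = FALSE)
  }
  act <- !epochs$missing & !is.na(epochs$segment_category) &
    epochs$segment_category == "activity"
  kcal <- vo2_to_kcal(epochs$vo2_rate[act] / 1000) * epoch / 60
  list(gross_aee = sum(kcal), active_minutes = sum(act) * epoch / 60)
}

# Schofield weight-only coefficients (kcal/day): intercept + slope * kg,
# by sex and age band (3-10 y, 10-18 y).
SCHOFIELD_COEF <- list(
  male = list(child = c(slope = 22.7, intercept = 495),
              adolescent = c(slope = 17.5, intercept = 651)),
  female = list(child = c(slope = 22.5, intercept = 499),
                adolescent = c(slope = 12.2, intercept = 746))
)

#' Schofield basal metabolic rate for children and adolescents
#'
#' Weight-only Schofield equations, kcal/day, with the 3-10 y and 10-18 y
#' bands; age 10 falls in the adolescent band. The coefficients are stored
#' as named constants (`SCHOFIELD_COEF`).
#'
#' @param subject A `subject_profile`, or a sex string when `age` and
#'   `weight` are given explicitly.
#' @param age Age in years (3 <= age < 18).
#' @param weight Body weight in kg (> 0).
#' @return Predicted BMR in kcal/day.
#' @export
#' @examples
#' schofield_bmr("male", age = 9, weight = 32)   # 22.7 * 32 + 495
schofield_bmr <- function(subject, age = NULL, weight = NULL) {
  if (is.list(subject)) {
    validate_subject(subject)
    sex <- subject$sex
    age <- subject$age
    weight <- subject$weight
  } else {
    sex <- match.arg(subject, c("male", "female"))
  }
  if (is.null(age) || age < 3 || age >= 18) {
    stop("Schofield child/adolescent bands require 3 <= age < 18",
         call. = FALSE)
  }
  if (is.null(weight) || weight <= 0) {
    stop("weight must be positive", call. = FALSE)
  }
  band <- if (age < 10) "child" else "adolescent"
  cf <- SCHOFIELD_COEF[[sex]][[band]]
  unname(cf["slope"] * weight + cf["intercept"])
}

#' Net activity energy expenditure
#'
#' Subtracts basal energy during active time from gross active energy:
#' `net = gross - (bmr_daily / 1440) * active_minutes`. A negative result
#' (possible when activity barely exceeds basal) is returned with a
#' warning, not clamped.
#'
#' @param gross_aee Gross active energy, kcal (>= 0).
#' @param bmr_daily Basal metabolic rate, kcal/day (>= 0).
#' @param active_minutes Active time, minutes (>= 0).
#' @return Net AEE in kcal.
#' @export
#' @examples
#' net_aee(100, 1440, 40)  # 60
net_aee <- function(gross_aee, bmr_daily, active_minutes) {
  stop_if_not_scalar_number(gross_aee, "gross_aee", min = 0)
  stop_if_not_scalar_number(bmr_daily, "bmr_daily", min = 0)
  stop_if_not_scalar_number(active_minutes, "active_minutes", min = 0)
  net <- gross_aee - bmr_daily / 1440 * active_minutes
  if (net < 0) {
    warning("net AEE is negative (activity energy below basal rate)",
            call. = FALSE)
  }
  net
}

#' Run the full laboratory criterion arm for one session
#'
#' Breath records to epochs, segment alignment, individualized resting
#' 1-MET, MET classification, MVPA minutes, and gross/net AEE with
#' Schofield BMR.
#'
#' @param breaths Breath series (see [simulate_gas_exchange()] or
#'   [read_breath_table()]).
#' @param protocol The session's [make_lab_protocol()] table.
#' @param subject The `subject_profile` measured.
#' @param epoch Epoch length in seconds (default 60).
#' @return A list of class `lab_result`: `mvpa` (min), `gross_aee`,
#'   `net_aee` (kcal), `bmr_daily` (kcal/day), `active_minutes`,
#'   `resting` (the 1-MET baseline), and the per-epoch table `epochs`.
#' @export
process_lab_session <- function(breaths, protocol, subject, epoch = 60) {
  validate_subject(subject)
  ep <- aggregate_breaths(breaths, epoch = epoch,
                          session_end = attr(protocol, "total_s") %||%
                            max(protocol$end))
  ep <- assign_epoch_segments(ep, protocol, epoch = epoch)
  resting <- compute_resting_met(ep, protocol, subject$weight, epoch = epoch)
  ep <- mets_from_vo2(ep, resting, subject$weight)
  ep$intensity <- classify_met_intensity(pmax(0, ep$met))
  mvpa <- mvpa_minutes(ep, epoch = epoch)
  aee <- gross_active_aee(ep, epoch = epoch)
  bmr <- schofield_bmr(subject)
  net <- net_aee(aee$gross_aee, bmr, aee$active_minutes)
  structure(list(subject_id = subject$subject_id, mvpa = mvpa,
                 gross_aee = aee$gross_aee, net_aee = net,
                 bmr_daily = bmr, active_minutes = aee$active_minutes,
                 resting = resting, epochs = ep),
            class = "lab_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
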