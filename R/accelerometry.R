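#' Named ENMO intensity cut-point sets
#'
#' Threshold sets are data, not logic: the default set
#' `"hildebrand_children_wrist"` carries the Hildebrand ENMO thresholds for
#' children wearing an ActiGraph on the wrist (light 35.6 mg, moderate
#' 201.4 mg, vigorous 707.0 mg). Custom thresholds can be given directly.
#'
#' @param name Name of a shipped set, or `"custom"` with explicit values.
#' @param lpa_threshold,mpa_threshold,vpa_threshold Thresholds in milli-g
#'   for a custom set; must satisfy `0 < lpa < mpa < vpa`.
#' @return A list of class `cut_points` with the three thresholds and the
#'   set name.
#' @export
#' @examples
#' cut_points()$mpa_threshold  # 201.4
cut_points <- function(name = "hildebrand_children_wrist",
                       lpa_threshold = NULL, mpa_threshold = NULL,
                       vpa_threshold = NULL) {
  sets <- list(
    hildebrand_children_wrist = c(lpa = 35.6, mpa = 201.4, vpa = 707.0)
  )
  if (name == "custom") {
    v <- c(lpa = lpa_threshold, mpa = mpa_threshold, vpa = vpa_threshold)
  } else if (name %in% names(sets)) {
    v <- sets[[name]]
  } else {
    stop(sprintf("unknown cut-point set \"%s\"", name), call. = FALSE)
  }
  if (length(v) != 3 || !(v[["lpa"]] > 0 && v[["lpa"]] < v[["mpa"]] &&
                          v[["mpa"]] < v[["vpa"]])) {
    stop("cut-points must satisfy 0 < lpa < mpa < vpa", call. = FALSE)
  }
  structure(list(lpa_threshold = v[["lpa"]], mpa_threshold = v[["mpa"]],
                 vpa_threshold = v[["vpa"]], name = name),
            class = "cut_points")
}

#' Auto-calibrate raw acceleration against local gravity
#'
#' Detects stationary 10-s windows (per-axis SD below `sd_threshold_mg`)
#' and fits a per-axis offset and gain by iteratively regressing each
#' window's mean vector onto its closest point on the unit sphere, so that
#' calibrated stationary norms approach 1 g. A simplified offset+gain
#' least-squares scheme; no temperature term. When fewer than
#' `min_orientations` distinct stationary orientations are present the
#' geometry cannot identify the model and an identity model is returned
#' with `converged = FALSE`.
#'
#' @param samples Raw samples (`time_s`, `x_g`, `y_g`, `z_g`).
#' @param rate Sampling rate in Hz.
#' @param window_s Stationary window length, seconds.
#' @param sd_threshold_mg Per-axis SD threshold (milli-g) defining
#'   stationarity.
#' @param min_orientations Minimum count of distinct stationary
#'   orientations (pairwise separation > 50 mg) for a fit.
#' @param max_iter,tol Iteration controls for the alternating fit.
#' @return A list of class `calibration_model` with `offset` (g), `gain`,
#'   `n_stationary_windows`, and `converged`.
#' @export
autocalibrate <- function(samples, rate, window_s = 10, sd_threshold_mg = 13,
                          min_orientations = 3, max_iter = 100,
                          tol = 1e-10) {
  if (is.null(samples) || nrow(samples) == 0) {
    stop("`samples` is empty", call. = FALSE)
  }
  if (nrow(samples) < 600 * rate) {
    stop("need at least 10 minutes of data to calibrate", call. = FALSE)
  }
  xyz <- as.matrix(samples[, c("x_g", "y_g", "z_g")])
  win <- floor((samples$time_s - samples$time_s[1]) / window_s)
  u <- sort(unique(win))
  n_per <- tabulate(win + 1L)[u + 1L]
  means <- rowsum(xyz, win) / n_per
  sq <- rowsum(xyz^2, win) / n_per
  sds <- sqrt(pmax(sq - means^2, 0))
  full <- n_per >= round(rate * window_s)  # complete windows only
  stat <- full & apply(sds, 1, function(r) all(r < sd_threshold_mg / 1000))
  M <- means[stat, , drop = FALSE]

  identity_model <- function(n) {
    structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                   n_stationary_windows = n, converged = FALSE),
              class = "calibration_model")
  }
  if (nrow(M) == 0) return(identity_model(0))
  if (count_distinct_orientations(M) < min_orientations) {
    return(identity_model(nrow(M)))
  }

  off <- c(0, 0, 0)
  gain <- c(1, 1, 1)
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(M, 2, gain, `*`), 2, off, `+`)
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm
    new_off <- off
    new_gain <- gain
    for (j in 1:3) {
      fit <- stats::lm.fit(cbind(1, M[, j]), target[, j])
      new_off[j] <- fit$coefficients[1]
      new_gain[j] <- fit$coefficients[2]
    }
    delta <- max(abs(new_off - off), abs(new_gain - gain))
    off <- new_off
    gain <- new_gain
    if (delta < tol) break
  }
  converged <- all(gain > 0.5 & gain < 2)
  structure(list(offset = off, gain = gain,
                 n_stationary_windows = nrow(M),
                 converged = converged),
            class = "calibration_model")
}

# Greedy count of window-mean vectors separated by > 50 mg.
count_distinct_orientations <- function(M, min_dist = 0.05) {
  picked <- M[1, , drop = FALSE]
  for (i in seq_len(nrow(M))[-1]) {
    d <- sqrt(rowSums((picked - matrix(M[i, ], nrow(picked), 3,
                                       byrow = TRUE))^2))
    if (all(d > min_dist)) picked <- rbind(picked, M[i, ])
  }
  nrow(picked)
}

#' Apply a calibration model to raw samples
#'
#' @param samples Raw samples (`x_g`, `y_g`, `z_g`).
#' @param model A [autocalibrate()] result.
#' @return `samples` with calibrated axes
#'   (`calibrated = offset + gain * raw` per axis).
#' @export
apply_calibration <- function(samples, model) {
  stopifnot(inherits(model, "calibration_model"))
  for (j in seq_along(c("x_g", "y_g", "z_g"))) {
    col <- c("x_g", "y_g", "z_g")[j]
    samples[[col]] <- model$offset[j] + model$gain[j] * samples[[col]]
  }
  samples
}

#' Per-epoch ENMO from calibrated samples
#'
#' ENMO (Euclidean norm minus one) per sample is
#' `max(0, sqrt(x^2 + y^2 + z^2) - 1)` in g -- the truncation at zero is
#' applied per sample, before averaging, so sub-gravity samples do not
#' cancel supra-gravity ones. Epoch values are per-sample means reported in
#' milli-g. Epochs containing no samples are flagged missing.
#'
#' @param samples Calibrated samples (`time_s`, `x_g`, `y_g`, `z_g`).
#' @param epoch Epoch length in seconds (default 60).
#' @param start_time Start of the epoch grid (s); defaults to the first
#'   sample's epoch floor.
#' @param end_time End of the covered span; defaults past the last sample.
#' @return A `data.frame` with `minute_start` (s), `enmo_mg`, `n_samples`,
#'   and `missing`.
#' @export
#' @examples
#' s <- data.frame(time_s = (0:59), x_g = 0, y_g = 0, z_g = 2)
#' compute_enmo(s, epoch = 60)$enmo_mg  # 1000
compute_enmo <- function(samples, epoch = 60, start_time = NULL,
                         end_time = NULL) {
  if (is.null(samples) || nrow(samples) == 0) {
    stop("`samples` is empty", call. = FALSE)
  }
  stop_if_not_scalar_number(epoch, "epoch", min = 0, closed_min = FALSE)
  if (is.null(start_time)) {
    start_time <- floor(samples$time_s[1] / epoch) * epoch
  }
  if (is.null(end_time)) end_time <- max(samples$time_s) + 1e-9
  e <- pmax(0, sqrt(samples$x_g^2 + samples$y_g^2 + samples$z_g^2) - 1)
  idx <- floor((samples$time_s - start_time) / epoch)
  n_epochs <- max(1, ceiling((end_time - start_time) / epoch))
  keep <- idx >= 0 & idx < n_epochs
  counts <- tabulate(idx[keep] + 1L, nbins = n_epochs)
  sums <- rep(0, n_epochs)
  agg <- rowsum(e[keep], idx[keep])
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  enmo <- ifelse(counts > 0, sums / pmax(counts, 1L) * 1000, NA_real_)
  data.frame(minute_start = start_time + (seq_len(n_epochs) - 1) * epoch,
             enmo_mg = enmo, n_samples = counts, missing = counts == 0)
}

#' Classify per-epoch ENMO into intensity classes
#'
#' Left-closed bands: SED below the light threshold, LPA from light up to
#' (not including) moderate, MPA from moderate up to vigorous, VPA at or
#' above vigorous.
#'
#' @param records Output of [compute_enmo()].
#' @param cuts A [cut_points()] set.
#' @return `records` with an `intensity` factor column.
#' @export
classify_enmo <- function(records, cuts = cut_points()) {
  stopifnot(inherits(cuts, "cut_points"))
  e <- records$enmo_mg
  cls <- ifelse(e < cuts$lpa_threshold, "SED",
                ifelse(e < cuts$mpa_threshold, "LPA",
                       ifelse(e < cuts$vpa_threshold, "MPA", "VPA")))
  records$intensity <- factor(cls, levels = c("SED", "LPA", "MPA", "VPA"))
  records
}

#' Detect monitor non-wear from per-minute activity (Choi run-length rule)
#'
#' A minute is non-wear when it lies inside a span of at least `window`
#' minutes of zero activity, where interruptions of at most
#' `spike_tolerance` consecutive non-zero minutes are tolerated provided
#' each interruption is flanked by at least `flank` consecutive zero
#' minutes on both sides. "Zero" means activity below `zero_threshold`
#' (default 1 mg of ENMO; the rule was defined on counts, and the
#' threshold adapts it to the ENMO signal).
#'
#' @param x Numeric per-minute activity values (mg), contiguous in time.
#' @param window Minimum non-wear span, minutes (default 90).
#' @param spike_tolerance Maximum tolerated interruption, minutes
#'   (default 2).
#' @param flank Required zero run on each side of an interruption, minutes
#'   (default 30).
#' @param zero_threshold Activity level counted as zero, mg (default 1).
#' @return Logical wear vector (`TRUE` = worn), same length as `x`.
#' @export
#' @examples
#' x <- c(rep(10, 5), rep(0, 95), rep(10, 5))
#' sum(!detect_nonwear(x))  # 95
detect_nonwear <- function(x, window = 90, spike_tolerance = 2, flank = 30,
                           zero_threshold = 1) {
  n <- length(x)
  wear <- rep(TRUE, n)
  if (n < window) return(wear)
  zero <- ifelse(is.na(x), TRUE, x < zero_threshold)
  r <- rle(zero)
  len <- r$lengths
  val <- r$values
  ends <- cumsum(len)
  starts <- ends - len + 1L
  k <- length(len)
  i <- 1L
  while (i <= k) {
    if (!val[i]) {
      i <- i + 1L
      next
    }
    # chain zero runs linked by tolerated spikes
    j <- i
    while (j + 2L <= k &&
           !val[j + 1L] && len[j + 1L] <= spike_tolerance &&
           val[j + 2L] &&
           len[j] >= flank && len[j + 2L] >= flank) {
      j <- j + 2L
    }
    span_len <- ends[j] - starts[i] + 1L
    if (span_len >= window) {
      wear[starts[i]:ends[j]] <- FALSE
    }
    i <- j + 1L
  }
  wear
}

#' Exclude logged sleep and non-wear intervals
#'
#' Marks minutes overlapping any parent-reported sleep or non-wear interval
#' as excluded, in addition to algorithmic non-wear. Intervals are clipped
#' to the recording span.
#'
#' @param records Minute records with `minute_start` (seconds from local
#'   midnight of `start_date`).
#' @param log Log table (`date`, `start_hms`, `end_hms`, `kind`); see
#'   [read_activity_log()].
#' @param start_date `Date` corresponding to second 0 of `minute_start`.
#' @return `records` with a logical `excluded_by_log` column (existing
#'   exclusions are kept; adding intervals never un-excludes a minute).
#' @export
apply_logs <- function(records, log, start_date) {
  excl <- records$excluded_by_log %||% rep(FALSE, nrow(records))
  if (!is.null(log) && nrow(log) > 0) {
    s <- as.numeric(as.Date(log$date) - as.Date(start_date)) * 86400 +
      hms_to_seconds(log$start_hms)
    e <- as.numeric(as.Date(log$date) - as.Date(start_date)) * 86400 +
      hms_to_seconds(log$end_hms)
    if (any(e <= s)) {
      stop("log intervals must have end after start", call. = FALSE)
    }
    for (i in seq_along(s)) {
      hit <- records$minute_start < e[i] & records$minute_start + 60 > s[i]
      excl <- excl | hit
    }
  }
  records$excluded_by_log <- excl
  records
}

hms_to_seconds <- function(hms) {
  p <- strsplit(hms, ":", fixed = TRUE)
  vapply(p, function(v) sum(as.numeric(v) * c(3600, 60, 1)[seq_along(v)]),
         numeric(1))
}

#' Daily MVPA summaries from classified minute records
#'
#' Splits minutes into local-midnight calendar days, counts worn,
#' non-excluded minutes by intensity, drops days with wear time below
#' `wear_min`, and averages daily MVPA over the retained days.
#'
#' @param records Minute records with `minute_start`, `intensity`, `wear`,
#'   and `excluded_by_log` columns.
#' @param wear_min Minimum wear minutes for a day to be retained
#'   (default 600).
#' @return A list with `daily` (per-day `day`, `mvpa`, `total_pa`,
#'   `wear_minutes`, `retained`) and `mean_mvpa`, the mean over retained
#'   days.
#' @export
daily_mvpa <- function(records, wear_min = 600) {
  stopifnot(all(c("minute_start", "intensity", "wear") %in% names(records)))
  excl <- records$excluded_by_log %||% rep(FALSE, nrow(records))
  use <- records$wear & !excl & !is.na(records$intensity)
  day <- floor(records$minute_start / 86400)
  days <- sort(unique(day))
  daily <- data.frame(
    day = days,
    mvpa = vapply(days, function(d) {
      sum(use & day == d & records$intensity %in% c("MPA", "VPA"))
    }, numeric(1)),
    total_pa = vapply(days, function(d) {
      sum(use & day == d & records$intensity != "SED")
    }, numeric(1)),
    wear_minutes = vapply(days, function(d) sum(use & day == d), numeric(1))
  )
  daily$retained <- daily$wear_minutes >= wear_min
  if (!any(daily$retained)) {
    stop("no days meet the minimum wear time", call. = FALSE)
  }
  list(daily = daily, mean_mvpa = mean(daily$mvpa[daily$retained]))
}
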