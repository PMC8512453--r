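#' Simulate a free-living week plan with known ground truth
#'
#' Builds a minute-aligned multi-day schedule for one subject: a nightly
#' sleep window (devices off), a midday non-wear bout of 95 min, morning
#' and afternoon MVPA bouts, and light/sedentary filler, mirroring a
#' school-aged child's week. The requested mean daily MVPA is realized as
#' whole minutes: `round(days * daily_mvpa_min)` MVPA minutes are spread
#' across days (first days absorb the remainder), so per-day truth is an
#' integer and the weekly truth mean is within half a minute of the
#' request. Parent-reported sleep and non-wear intervals are returned as a
#' log table, and per-day device summaries are drawn from the truth with
#' the `device_*` parameters.
#'
#' The raw acceleration stream is not materialized here (a week at 30 Hz is
#' ~18 million samples); feed single days of `$schedule` to
#' [simulate_raw_accel()], as [run_freeliving_validation()] does, to keep
#' memory flat.
#'
#' @param subject A [make_subject()] profile.
#' @param params A [sim_params()] object.
#' @param days Number of days (>= 1, default 7).
#' @param daily_mvpa_min Target mean daily MVPA in minutes (default 53.3).
#' @param start_date `Date` of day 1 (used for log and daily dates).
#' @return A list of class `free_living_week` with `$schedule` (segments:
#'   `day`, `start`, `end` seconds from day-1 midnight, `wear`,
#'   `target_met`, `kind`), `$log` (`date`, `start_hms`, `end_hms`,
#'   `kind`), `$truth_daily` (`date`, `day`, `true_mvpa`, `true_total_pa`,
#'   `wear_minutes`), `$device_daily` (per-day device MVPA), `$subject`,
#'   `$days`, `$start_date`.
#' @export
#' @examples
#' wk <- simulate_free_living_week(make_subject(1), sim_params(seed = 3),
#'                                 days = 2)
#' wk$truth_daily
simulate_free_living_week <- function(subject, params = sim_params(),
                                      days = 7, daily_mvpa_min = 53.3,
                                      start_date = as.Date("2021-04-05")) {
  validate_subject(subject)
  stop_if_not_scalar_number(days, "days", min = 1)
  stop_if_not_scalar_number(daily_mvpa_min, "daily_mvpa_min", min = 0)
  days <- as.integer(days)

  total <- round(days * daily_mvpa_min)
  base <- total %/% days
  extra <- total - base * days
  day_mvpa <- base + as.integer(seq_len(days) <= extra)

  sched <- do.call(rbind, lapply(seq_len(days), function(d) {
    fl_day_schedule(d - 1L, day_mvpa[d])
  }))

  dates <- start_date + (seq_len(days) - 1L)
  log <- do.call(rbind, lapply(seq_len(days), function(d) {
    data.frame(date = rep(dates[d], 3),
               start_hms = c("00:00:00", "12:30:00", "21:30:00"),
               end_hms = c("07:30:00", "14:05:00", "24:00:00"),
               kind = c("sleep", "nonwear", "sleep"),
               stringsAsFactors = FALSE)
  }))

  worn <- sched$wear
  min_per_seg <- (sched$end - sched$start) / 60
  pa <- worn & sched$target_met > 1.5
  truth_daily <- data.frame(
    date = dates, day = seq_len(days) - 1L,
    true_mvpa = day_mvpa,
    true_total_pa = vapply(seq_len(days) - 1L, function(d) {
      sum(min_per_seg[pa & sched$day == d])
    }, numeric(1)),
    wear_minutes = vapply(seq_len(days) - 1L, function(d) {
      sum(min_per_seg[worn & sched$day == d])
    }, numeric(1))
  )

  device <- simulate_device_summary(
    list(subject_id = subject$subject_id, true_mvpa = day_mvpa), params)
  device$date <- dates

  structure(list(subject = subject, schedule = sched, log = log,
                 truth_daily = truth_daily, device_daily = device,
                 days = days, start_date = start_date),
            class = "free_living_week")
}

# One day's minute-aligned segments. `day` is 0-based; minutes are turned
# into absolute seconds from day-1 midnight. The MVPA allocation is split
# into a morning bout (4.5 MET) and an afternoon bout (6.5 MET).
fl_day_schedule <- function(day, mvpa_min) {
  stopifnot(mvpa_min >= 0, mvpa_min <= 120)
  m1 <- mvpa_min %/% 2
  m2 <- mvpa_min - m1
  blocks <- rbind(
    c(0, 450, NA, 0),        # sleep, device off
    c(450, 510, 2.0, 1),     # morning light activity
    c(510, 540, 1.3, 1),     # sedentary (breakfast, reading)
    c(540, 540 + m1, 4.5, 1),  # morning MVPA bout
    c(540 + m1, 645, 1.3, 1),
    c(645, 750, 2.0, 1),
    c(750, 845, NA, 0),      # midday non-wear bout (95 min, logged)
    c(845, 860, 2.0, 1),
    c(860, 860 + m2, 6.5, 1),  # afternoon vigorous bout
    c(860 + m2, 1000, 1.3, 1),
    c(1000, 1100, 2.0, 1),
    c(1100, 1200, 1.3, 1),
    c(1200, 1290, 2.0, 1),
    c(1290, 1440, NA, 0)     # evening sleep
  )
  blocks <- blocks[blocks[, 2] > blocks[, 1], , drop = FALSE]
  kind <- ifelse(is.na(blocks[, 3]), ifelse(blocks[, 1] %in% c(0, 1290),
                                            "sleep", "nonwear"),
                 ifelse(blocks[, 3] >= 3, "mvpa",
                        ifelse(blocks[, 3] > 1.5, "light", "sedentary")))
  data.frame(day = day,
             start = day * 86400 + blocks[, 1] * 60,
             end = day * 86400 + blocks[, 2] * 60,
             wear = blocks[, 4] == 1,
             target_met = blocks[, 3],
             kind = kind,
             stringsAsFactors = FALSE)
}
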