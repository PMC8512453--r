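#' Build a laboratory activity protocol
#'
#' Constructs the segment table for a lab session: an initial inclined rest,
#' then `n_activities` free-living-style activity stations, each preceded by
#' a short transition (walking to the next station). Station MET targets
#' span sedentary through vigorous, with at least one station per intensity
#' class at the default length.
#'
#' By default station durations are whole minutes chosen so the session
#' totals `total_min` (50 min at the defaults: 3 min rest, 14 stations, 14
#' one-minute transitions, 33 station-minutes). Whole-minute segments keep
#' every boundary aligned with 60-s analysis epochs, which makes noiseless
#' simulations recover their programmed summaries exactly.
#'
#' @param n_activities Number of activity stations (>= 1).
#' @param rest_min Initial rest duration, minutes.
#' @param transition_min Transition duration before each station, minutes.
#' @param activity_min Optional single station duration in minutes; if
#'   `NULL`, durations are allocated in whole minutes to hit `total_min`.
#' @param activity_mets MET target per station; defaults to a 14-value set
#'   drawn from typical children's activities (TV viewing through running),
#'   recycled if `n_activities` differs from 14.
#' @param total_min Target session length in minutes used when
#'   `activity_min` is `NULL`.
#' @param rest_met,transition_met MET targets for rest and transitions.
#' @return A `data.frame` of class `lab_protocol` with columns `label`,
#'   `start`, `end` (seconds from session start), `category`
#'   (`rest`/`sedentary`/`activity`/`transition`) and `target_met`, plus a
#'   `total_s` attribute with the session length in seconds.
#' @export
#' @examples
#' p <- make_lab_protocol()
#' sum(p$category == "activity") + sum(p$category == "sedentary")  # 14
#' attr(p, "total_s") / 60                                         # 50
make_lab_protocol <- function(n_activities = 14, rest_min = 3,
                              transition_min = 1, activity_min = NULL,
                              activity_mets = NULL, total_min = 50,
                              rest_met = 1.0, transition_met = 2.0) {
  stop_if_not_scalar_number(n_activities, "n_activities", min = 1)
  stop_if_not_scalar_number(rest_min, "rest_min", min = 0, closed_min = FALSE)
  stop_if_not_scalar_number(transition_min, "transition_min", min = 0,
                            closed_min = FALSE)
  n_activities <- as.integer(n_activities)

  if (is.null(activity_mets)) {
    # Typical children's stations: two sedentary, four light, six moderate,
    # two vigorous targets; values sit away from the 1.5/3.0/6.0 MET cuts.
    base <- c(1.3, 2.0, 3.5, 1.4, 2.5, 4.0, 5.0, 2.2, 3.8, 6.5, 2.8, 4.5,
              7.5, 5.5)
    activity_mets <- rep_len(base, n_activities)
  }
  stopifnot(length(activity_mets) == n_activities, all(activity_mets >= 0.9))

  if (is.null(activity_min)) {
    avail <- total_min - rest_min - n_activities * transition_min
    if (avail <= 0) {
      stop("`total_min` leaves no time for activity stations", call. = FALSE)
    }
    if (abs(avail - round(avail)) < 1e-9 && avail >= n_activities) {
      base_d <- floor(avail / n_activities)
      extra <- round(avail) - base_d * n_activities
      durations <- rep(base_d, n_activities)
      if (extra > 0) durations[seq_len(extra)] <- base_d + 1
    } else {
      durations <- rep(avail / n_activities, n_activities)
    }
  } else {
    stop_if_not_scalar_number(activity_min, "activity_min", min = 0,
                              closed_min = FALSE)
    durations <- rep(activity_min, n_activities)
  }

  label <- "rest"
  start <- 0
  end <- rest_min * 60
  category <- "rest"
  met <- rest_met
  t <- end
  for (i in seq_len(n_activities)) {
    label <- c(label, sprintf("transition_%02d", i), sprintf("activity_%02d", i))
    start <- c(start, t, t + transition_min * 60)
    t <- t + (transition_min + durations[i]) * 60
    end <- c(end, start[length(start)], t)
    category <- c(category, "transition",
                  if (activity_mets[i] <= 1.5) "sedentary" else "activity")
    met <- c(met, transition_met, activity_mets[i])
  }
  out <- data.frame(label = label, start = start, end = end,
                    category = category, target_met = met,
                    stringsAsFactors = FALSE)
  validate_protocol(out)
  structure(out, total_s = t, class = c("lab_protocol", "data.frame"))
}

validate_protocol <- function(protocol) {
  stopifnot(is.data.frame(protocol), nrow(protocol) >= 1,
            all(c("start", "end", "category", "target_met") %in%
                  names(protocol)))
  if (any(protocol$end <= protocol$start)) {
    stop("protocol segments must have end > start", call. = FALSE)
  }
  if (is.unsorted(protocol$start, strictly = TRUE) ||
      any(protocol$start[-1] < protocol$end[-nrow(protocol)] - 1e-9)) {
    stop("protocol segments must be ordered and non-overlapping",
         call. = FALSE)
  }
  invisible(protocol)
}

#' Ground-truth summaries implied by a lab protocol
#'
#' Computes the quantities the lab pipeline should recover in a noiseless
#' simulation: MVPA minutes (total duration of segments with
#' `target_met >= 3`), active minutes, gross active energy expenditure from
#' the MET targets, Schofield basal metabolic rate, and net AEE.
#'
#' @param protocol A [make_lab_protocol()] segment table.
#' @param subject A [make_subject()] profile.
#' @param params A [sim_params()] object (supplies the resting VO2 used by
#'   the simulator).
#' @return A list of class `truth_record` with `subject_id`, `true_mvpa`
#'   (min), `true_gross_aee`, `true_net_aee` (kcal), `active_minutes`,
#'   `bmr_daily` (kcal/day) and `segment_mets`.
#' @export
lab_protocol_truth <- function(protocol, subject, params = sim_params()) {
  validate_protocol(protocol)
  validate_subject(subject)
  dur_min <- (protocol$end - protocol$start) / 60
  true_mvpa <- sum(dur_min[protocol$target_met >= 3.0])
  active <- protocol$category == "activity"
  # kcal/min at a MET target: met * resting VO2 (mL/kg/min) * kg -> mL/min,
  # /1000 -> L/min, * 4.867 kcal/L.
  kcal_min <- protocol$target_met * params$resting_vo2_per_kg *
    subject$weight / 1000 * KCAL_PER_L_O2
  gross <- sum((kcal_min * dur_min)[active])
  active_minutes <- sum(dur_min[active])
  bmr <- schofield_bmr(subject)
  net <- gross - bmr / 1440 * active_minutes
  structure(list(
    subject_id = subject$subject_id,
    true_mvpa = true_mvpa,
    true_gross_aee = gross,
    true_net_aee = net,
    active_minutes = active_minutes,
    bmr_daily = bmr,
    segment_mets = stats::setNames(protocol$target_met, protocol$label)
  ), class = "truth_record")
}
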