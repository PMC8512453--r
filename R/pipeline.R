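#' Run configuration for the validation pipelines
#'
#' Bundles every pipeline parameter with its default: cohort sizes match
#' the study design (20 lab subjects, a 5-child free-living subsample over
#' 7 days at 30 Hz), 60-s epochs, Hildebrand children's wrist cut-points,
#' Choi non-wear defaults (90/2/30 min), a 600-min wear minimum, 90%
#' confidence for equivalence, and the reporting sign conventions of the
#' two arms (criterion - device in the lab, device - criterion in free
#' living).
#'
#' @param seed Global integer seed.
#' @param n_subjects Lab cohort size.
#' @param n_freeliving Free-living subsample size.
#' @param days Free-living days per subject.
#' @param rate Accelerometer sampling rate, Hz.
#' @param epoch_s Epoch length, seconds.
#' @param cuts Cut-point set name for [cut_points()].
#' @param choi Choi parameters (`window`, `spike_tolerance`, `flank`,
#'   `zero_threshold`).
#' @param wear_min Minimum daily wear minutes to retain a day.
#' @param ci_level Confidence level for the equivalence interval.
#' @param direction_lab,direction_freeliving Bias sign conventions.
#' @param daily_mvpa_min Programmed mean daily free-living MVPA, minutes.
#' @param params A [sim_params()] object; defaults to `sim_params(seed =
#'   seed)`.
#' @param calibrate Whether the free-living arm fits an autocalibration
#'   model on each subject's first day.
#' @param out_dir Optional directory for report files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_subjects = 20, n_freeliving = 5,
                       days = 7, rate = 30, epoch_s = 60,
                       cuts = "hildebrand_children_wrist",
                       choi = list(window = 90, spike_tolerance = 2,
                                   flank = 30, zero_threshold = 1),
                       wear_min = 600, ci_level = 0.90,
                       direction_lab = "criterion_minus_device",
                       direction_freeliving = "device_minus_criterion",
                       daily_mvpa_min = 53.3,
                       params = sim_params(seed = seed),
                       calibrate = TRUE, out_dir = NULL) {
  stop_if_not_scalar_number(n_subjects, "n_subjects", min = 1)
  stop_if_not_scalar_number(n_freeliving, "n_freeliving", min = 1)
  stop_if_not_scalar_number(ci_level, "ci_level", min = 0, max = 1,
                            closed_min = FALSE, closed_max = FALSE)
  stopifnot(inherits(params, "sim_params"))
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 n_freeliving = n_freeliving, days = days, rate = rate,
                 epoch_s = epoch_s, cuts = cuts, choi = choi,
                 wear_min = wear_min, ci_level = ci_level,
                 direction_lab = direction_lab,
                 direction_freeliving = direction_freeliving,
                 daily_mvpa_min = daily_mvpa_min, params = params,
                 calibrate = calibrate, out_dir = out_dir),
            class = "run_config")
}

#' Simulate and validate the laboratory arm
#'
#' For each subject in a simulated cohort: generate the lab protocol and
#' breath-by-breath gas exchange, run the calorimetry criterion arm, pair
#' its MVPA minutes and net AEE with the simulated device summary, and
#' compute agreement (MAPE, mean bias, Bland-Altman) and equivalence
#' (minimal EZ around the criterion mean containing the device 90% CI)
#' for both metrics.
#'
#' @param config A [run_config()].
#' @return A list of class `validation_report` with `arm`, per-metric
#'   results under `metrics` (each holding `pairs`, `mape`, `bias`,
#'   `bland_altman`, `equivalence`, and summary means/SDs), and a
#'   provenance block. Written to `config$out_dir` when set.
#' @export
run_lab_validation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_subjects < 2) {
    stop("need at least 2 subjects for agreement statistics", call. = FALSE)
  }
  cohort <- make_cohort(config$n_subjects, seed = config$seed)
  protocol <- make_lab_protocol()
  rows <- lapply(cohort, function(s) {
    breaths <- simulate_gas_exchange(s, protocol, config$params)
    lab <- process_lab_session(breaths, protocol, s, epoch = config$epoch_s)
    truth <- lab_protocol_truth(protocol, s, config$params)
    dev <- simulate_device_summary(truth, config$params)
    data.frame(subject_id = s$subject_id,
               crit_mvpa = lab$mvpa, crit_aee = lab$net_aee,
               dev_mvpa = dev$mvpa_min, dev_aee = dev$aee_kcal,
               true_mvpa = truth$true_mvpa, true_aee = truth$true_net_aee)
  })
  tab <- do.call(rbind, rows)
  ok <- stats::complete.cases(tab)
  if (any(!ok)) {
    warning(sprintf("dropping %d unpaired subject(s)", sum(!ok)),
            call. = FALSE)
    tab <- tab[ok, ]
  }
  if (nrow(tab) < 2) stop("fewer than 2 paired subjects", call. = FALSE)

  metrics <- list(
    mvpa = metric_results(
      paired_measurements(tab$subject_id, tab$crit_mvpa, tab$dev_mvpa,
                          "mvpa_min"),
      config$direction_lab, config$ci_level),
    aee = metric_results(
      paired_measurements(tab$subject_id, tab$crit_aee, tab$dev_aee,
                          "aee_kcal"),
      config$direction_lab, config$ci_level)
  )
  report <- structure(list(arm = "lab", metrics = metrics, table = tab,
                           provenance = provenance(config)),
                      class = "validation_report")
  maybe_write_report(report, config)
  report
}

#' Process one subject's free-living week through the accelerometry arm
#'
#' Generates each day's raw acceleration from the week's schedule (keeping
#' only one day in memory at a time), optionally fits the calibration
#' model on day 1, computes per-minute ENMO, classifies intensity, applies
#' Choi non-wear detection over the whole contiguous week plus the logged
#' sleep/non-wear exclusions, and aggregates to daily MVPA.
#'
#' @param week A [simulate_free_living_week()] object.
#' @param config A [run_config()] (supplies rate, epoch, cut-points, Choi
#'   parameters, wear minimum).
#' @return A list with `records` (per-minute table), `daily`,
#'   `mean_mvpa`, and `calibration`.
#' @export
process_free_living <- function(week, config = run_config()) {
  stopifnot(inherits(week, "free_living_week"))
  cuts <- cut_points(config$cuts)
  model <- NULL
  recs <- vector("list", week$days)
  for (d in seq_len(week$days) - 1L) {
    day_sched <- week$schedule[week$schedule$day == d, , drop = FALSE]
    accel <- simulate_raw_accel(day_sched, config$params, rate = config$rate)
    if (is.null(model)) {
      model <- if (isTRUE(config$calibrate)) {
        autocalibrate(accel, rate = config$rate)
      } else {
        structure(list(offset = c(0, 0, 0), gain = c(1, 1, 1),
                       n_stationary_windows = 0, converged = FALSE),
                  class = "calibration_model")
      }
    }
    accel <- apply_calibration(accel, model)
    recs[[d + 1L]] <- compute_enmo(accel, epoch = config$epoch_s,
                                   start_time = d * 86400,
                                   end_time = (d + 1) * 86400)
  }
  records <- do.call(rbind, recs)
  records <- classify_enmo(records, cuts)
  records$wear <- detect_nonwear(
    records$enmo_mg, window = config$choi$window,
    spike_tolerance = config$choi$spike_tolerance,
    flank = config$choi$flank, zero_threshold = config$choi$zero_threshold)
  records <- apply_logs(records, week$log, week$start_date)
  agg <- daily_mvpa(records, wear_min = config$wear_min)
  list(records = records, daily = agg$daily, mean_mvpa = agg$mean_mvpa,
       calibration = model)
}

#' Simulate and validate the free-living arm
#'
#' For each subject of the free-living subsample: simulate a week, run the
#' raw-accelerometry criterion arm, average daily MVPA over retained days,
#' pair with the device's mean daily MVPA, and compute the agreement
#' statistics (the free-living comparison reports bias as device -
#' criterion, matching a device that over-reads).
#'
#' @param config A [run_config()].
#' @return A `validation_report` with the free-living MVPA metric.
#' @export
run_freeliving_validation <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- make_cohort(config$n_freeliving, seed = config$seed + 1000L)
  rows <- lapply(cohort, function(s) {
    week <- simulate_free_living_week(
      s, config$params, days = config$days,
      daily_mvpa_min = config$daily_mvpa_min)
    arm <- process_free_living(week, config)
    data.frame(subject_id = s$subject_id,
               crit_mvpa = arm$mean_mvpa,
               dev_mvpa = mean(week$device_daily$mvpa_min),
               true_mvpa = mean(week$truth_daily$true_mvpa),
               retained_days = sum(arm$daily$retained))
  })
  tab <- do.call(rbind, rows)
  if (nrow(tab) < 1 || all(tab$retained_days == 0)) {
    stop("no subjects with retained days", call. = FALSE)
  }
  pairs <- paired_measurements(tab$subject_id, tab$crit_mvpa, tab$dev_mvpa,
                               "daily_mvpa_min")
  metrics <- list(
    mvpa = metric_results(pairs, config$direction_freeliving,
                          config$ci_level)
  )
  report <- structure(list(arm = "freeliving", metrics = metrics,
                           table = tab, provenance = provenance(config)),
                      class = "validation_report")
  maybe_write_report(report, config)
  report
}

# Agreement + equivalence bundle for one paired metric; components whose
# sample-size preconditions are unmet are NULL rather than errors.
metric_results <- function(pairs, direction, ci_level) {
  n <- nrow(pairs)
  ci <- if (n >= 2) ci90(pairs$device, level = ci_level)
  list(
    metric = attr(pairs, "metric"),
    pairs = pairs,
    criterion_mean = mean(pairs$criterion),
    criterion_sd = sd(pairs$criterion),
    device_mean = mean(pairs$device),
    device_sd = sd(pairs$device),
    mape = mape(pairs),
    bias = if (n >= 2) mean_bias(pairs, direction),
    bland_altman = if (n >= 3) bland_altman(pairs, direction),
    device_ci = if (!is.null(ci)) as.numeric(ci),
    equivalence = if (!is.null(ci)) {
      minimal_equivalence_zone(as.numeric(ci), mean(pairs$criterion))
    }
  )
}

provenance <- function(config) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)
  list(package = "watchval",
       version = as.character(packageVersion("watchval")),
       seed = config$seed,
       config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))))
}

#' Write a validation report to disk
#'
#' Emits `report_<arm>.json` (all statistics), a summary table
#' `table_<arm>.csv` shaped like the study's results tables (criterion
#' mean (SD), device mean (SD), mean difference (SE), MAPE), and, for the
#' lab arm, Bland-Altman and equivalence figures.
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  slim <- report
  slim$metrics <- lapply(report$metrics, function(m) {
    if (!is.null(m$bland_altman)) {
      m$bland_altman$means <- NULL
      m$bland_altman$diffs <- NULL
      m$bland_altman <- unclass(m$bland_altman)
    }
    m$pairs <- as.data.frame(m$pairs)
    if (!is.null(m$equivalence)) m$equivalence <- unclass(m$equivalence)
    m
  })
  json_path <- file.path(dir, paste0("report_", report$arm, ".json"))
  jsonlite::write_json(unclass(slim), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, json_path)

  tab <- do.call(rbind, lapply(report$metrics, function(m) {
    data.frame(metric = m$metric,
               criterion_mean = round(m$criterion_mean, 1),
               criterion_sd = round(m$criterion_sd, 1),
               device_mean = round(m$device_mean, 1),
               device_sd = round(m$device_sd, 1),
               mean_diff = if (is.null(m$bias)) NA else round(m$bias$bias, 1),
               se_diff = if (is.null(m$bias)) NA else round(m$bias$se, 1),
               mape_pct = round(m$mape, 1),
               ez_pct = if (is.null(m$equivalence)) NA else
                 round(m$equivalence$ez_pct, 1))
  }))
  csv_path <- file.path(dir, paste0("table_", report$arm, ".csv"))
  write.csv(tab, csv_path, row.names = FALSE)
  paths <- c(paths, csv_path)

  for (nm in names(report$metrics)) {
    m <- report$metrics[[nm]]
    if (!is.null(m$bland_altman)) {
      ba_path <- file.path(dir, sprintf("bland_altman_%s_%s.png",
                                        report$arm, nm))
      ggplot2::ggsave(ba_path, plot_bland_altman(m$bland_altman),
                      width = 5, height = 4, dpi = 150)
      paths <- c(paths, ba_path)
    }
    if (!is.null(m$equivalence)) {
      eq_path <- file.path(dir, sprintf("equivalence_%s_%s.png",
                                        report$arm, nm))
      ggplot2::ggsave(eq_path, plot_equivalence(m$equivalence),
                      width = 5, height = 2.5, dpi = 150)
      paths <- c(paths, eq_path)
    }
  }
  invisible(paths)
}

maybe_write_report <- function(report, config) {
  if (!is.null(config$out_dir)) {
    write_validation_report(report, config$out_dir)
  }
  invisible(NULL)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation report: %s arm, n = %d>\n", x$arm,
              nrow(x$table)))
  for (m in x$metrics) {
    cat(sprintf(
      "  %s: criterion %.1f (%.1f), device %.1f (%.1f), MAPE %.1f%%",
      m$metric, m$criterion_mean, m$criterion_sd, m$device_mean,
      m$device_sd, m$mape))
    if (!is.null(m$bias)) {
      cat(sprintf(", bias %.1f (SE %.1f)", m$bias$bias, m$bias$se))
    }
    if (!is.null(m$equivalence)) {
      cat(sprintf(", EZ +/-%.1f%%", m$equivalence$ez_pct))
    }
    cat("\n")
  }
  invisible(x)
}
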