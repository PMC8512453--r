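#' Paired criterion/device measurements
#'
#' Light constructor and validator for the paired table every agreement
#' statistic consumes.
#'
#' @param subject_id Identifier per pair.
#' @param criterion,device Measurements in the metric's units (minutes or
#'   kcal).
#' @param metric Metric name (e.g. `"mvpa_min"`).
#' @return A `data.frame` of class `paired_measurements`.
#' @export
paired_measurements <- function(subject_id, criterion, device,
                                metric = "metric") {
  stopifnot(length(criterion) == length(device),
            length(subject_id) == length(criterion))
  if (any(!is.finite(criterion)) || any(!is.finite(device))) {
    stop("criterion and device values must be finite", call. = FALSE)
  }
  structure(data.frame(subject_id = subject_id, criterion = criterion,
                       device = device, stringsAsFactors = FALSE),
            metric = metric, class = c("paired_measurements", "data.frame"))
}

#' Mean absolute percent error
#'
#' `mean(|(criterion - device)/criterion|) * 100`, averaged over
#' participants (each pair is one participant).
#'
#' @param pairs A [paired_measurements()] table (or any data frame with
#'   `criterion` and `device` columns).
#' @return MAPE in percent.
#' @export
#' @examples
#' mape(paired_measurements(1:2, c(20, 10), c(19, 11)))  # 7.5
mape <- function(pairs) {
  if (any(pairs$criterion == 0)) {
    stop("MAPE is undefined when a criterion value is zero", call. = FALSE)
  }
  mean(abs((pairs$criterion - pairs$device) / pairs$criterion)) * 100
}

#' Signed bias between criterion and device values
#'
#' The elementary directed difference underlying every bias statistic.
#' With direction `"criterion_minus_device"` positive values mean the
#' device under-reads; `"device_minus_criterion"` is its exact negative.
#'
#' @param criterion,device Numeric vectors (recycled scalars allowed).
#' @param direction Difference direction.
#' @return Mean of the directed differences.
#' @export
#' @examples
#' signed_bias(20.2, 19.9)                               # 0.3
#' signed_bias(53.3, 78.6, "device_minus_criterion")     # 25.3
signed_bias <- function(criterion, device,
                        direction = c("criterion_minus_device",
                                      "device_minus_criterion")) {
  direction <- match.arg(direction)
  d <- if (direction == "criterion_minus_device") criterion - device
       else device - criterion
  mean(d)
}

#' Mean bias with paired t test
#'
#' Signed mean of per-pair differences in the requested direction, its
#' standard error, and the two-sided paired t probability with n - 1
#' degrees of freedom.
#'
#' @inheritParams mape
#' @inheritParams signed_bias
#' @return A list with `bias`, `se`, `p`, `n`, and `direction`.
#' @export
mean_bias <- function(pairs, direction = c("criterion_minus_device",
                                           "device_minus_criterion")) {
  direction <- match.arg(direction)
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 pairs for a bias estimate", call. = FALSE)
  d <- if (direction == "criterion_minus_device") {
    pairs$criterion - pairs$device
  } else {
    pairs$device - pairs$criterion
  }
  bias <- mean(d)
  se <- sd(d) / sqrt(n)
  p <- if (se == 0) {
    if (bias == 0) 1 else 0
  } else {
    2 * pt(-abs(bias / se), df = n - 1)
  }
  list(bias = bias, se = se, p = p, n = n, direction = direction)
}

#' Bland-Altman agreement components
#'
#' Mean bias, 95% limits of agreement (`bias +/- 1.96 sd` of the paired
#' differences), and the 95% t confidence interval of the bias. The
#' systematic-bias flag is `TRUE` when that confidence interval excludes
#' the line of equality (zero difference).
#'
#' @inheritParams mean_bias
#' @return A list of class `bland_altman` with `bias`, `se`, `sd_diff`,
#'   `loa_low`, `loa_high`, `bias_ci95`, `systematic_bias`, `p`, `n`,
#'   `direction`, and per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(pairs, direction = c("criterion_minus_device",
                                              "device_minus_criterion")) {
  direction <- match.arg(direction)
  n <- nrow(pairs)
  if (n < 3) {
    stop("need at least 3 pairs for limits of agreement", call. = FALSE)
  }
  mb <- mean_bias(pairs, direction)
  d <- if (direction == "criterion_minus_device") {
    pairs$criterion - pairs$device
  } else {
    pairs$device - pairs$criterion
  }
  s <- sd(d)
  ci <- mb$bias + c(-1, 1) * qt(0.975, df = n - 1) * mb$se
  structure(list(
    bias = mb$bias, se = mb$se, sd_diff = s,
    loa_low = mb$bias - 1.96 * s, loa_high = mb$bias + 1.96 * s,
    bias_ci95 = ci,
    systematic_bias = !(ci[1] <= 0 && 0 <= ci[2]),
    p = mb$p, n = n, direction = direction,
    means = (pairs$criterion + pairs$device) / 2, diffs = d
  ), class = "bland_altman")
}

#' Two-sided t confidence interval for a mean
#'
#' `mean +/- t(1 - (1 - level)/2, n - 1) * sd/sqrt(n)`; the default level
#' of 0.90 gives the 90% interval the equivalence analysis uses.
#'
#' @param values Numeric vector (>= 2 values).
#' @param level Confidence level (default 0.90).
#' @return Numeric `c(low, high)` with attributes `mean`, `level`, `n`.
#' @export
#' @examples
#' ci90(c(18, 20, 22, 19))
ci90 <- function(values, level = 0.90) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for an interval", call. = FALSE)
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  structure(c(m - half, m + half), mean = m, level = level, n = n)
}

#' Minimal relative equivalence zone
#'
#' The narrowest symmetric percent band around the criterion mean that
#' contains the device estimates' confidence interval:
#' `ez_pct = 100 * max(mean - ci_low, ci_high - mean) / mean`. The zone
#' bounds are `mean * (1 -/+ ez_pct/100)`, so the interval is contained by
#' construction (it touches the zone on its wider side). `ez_pct` is
#' returned at full precision; reports round it to one decimal.
#'
#' @param device_ci90 Numeric `c(low, high)` interval of device estimates
#'   (typically from [ci90()]).
#' @param criterion_mean Positive criterion mean in the same units.
#' @return A list of class `equivalence_result` with `device_ci90`,
#'   `criterion_mean`, `ez_pct`, `ez_bounds`, and `equivalent_within_ez`.
#' @export
#' @examples
#' ez <- minimal_equivalence_zone(c(16.63, 23.36), 20.2)
#' round(ez$ez_pct, 1)  # 17.7
minimal_equivalence_zone <- function(device_ci90, criterion_mean) {
  stop_if_not_scalar_number(criterion_mean, "criterion_mean", min = 0,
                            closed_min = FALSE)
  stopifnot(length(device_ci90) == 2, device_ci90[1] <= device_ci90[2])
  ez_pct <- 100 * max(criterion_mean - device_ci90[1],
                      device_ci90[2] - criterion_mean) / criterion_mean
  ez_bounds <- criterion_mean * (1 + c(-1, 1) * ez_pct / 100)
  structure(list(
    device_ci90 = as.numeric(device_ci90),
    criterion_mean = criterion_mean,
    ez_pct = ez_pct,
    ez_bounds = ez_bounds,
    equivalent_within_ez = equivalence_decision(device_ci90, ez_bounds)
  ), class = "equivalence_result")
}

#' Equivalence decision by interval inclusion
#'
#' `TRUE` when the device confidence interval lies within the equivalence
#' zone (closed inclusion, with a small numeric tolerance so a zone that
#' touches the interval counts as containing it).
#'
#' @param device_ci90 Numeric `c(low, high)` device interval.
#' @param ez_bounds Numeric `c(low, high)` equivalence-zone bounds.
#' @param tol Absolute tolerance for boundary contact.
#' @return Logical flag.
#' @export
equivalence_decision <- function(device_ci90, ez_bounds, tol = 1e-8) {
  stopifnot(length(device_ci90) == 2, length(ez_bounds) == 2)
  device_ci90[1] >= ez_bounds[1] - tol && device_ci90[2] <= ez_bounds[2] + tol
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "<equivalence> criterion mean %.2f; device 90%% CI (%.2f, %.2f)\n",
    x$criterion_mean, x$device_ci90[1], x$device_ci90[2]))
  cat(sprintf("  minimal EZ +/-%.1f%% (%.2f to %.2f); CI within EZ: %s\n",
              x$ez_pct, x$ez_bounds[1], x$ez_bounds[2],
              x$equivalent_within_ez))
  invisible(x)
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland-altman, %s> bias %.2f (95%% CI %.2f to %.2f), p %.3f\n",
              x$direction, x$bias, x$bias_ci95[1], x$bias_ci95[2], x$p))
  cat(sprintf("  95%% limits of agreement %.2f to %.2f; systematic bias: %s\n",
              x$loa_low, x$loa_high, x$systematic_bias))
  invisible(x)
}
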