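#' Bland-Altman plot
#'
#' Scatter of paired differences against paired means with the line of
#' equality (blue short-dashed), mean bias (solid), the 95% confidence
#' interval of the bias (red short-dashed), and the 95% limits of
#' agreement (dashed).
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  stopifnot(inherits(ba, "bland_altman"))
  df <- data.frame(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "blue",
                        linetype = "twodash") +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias_ci95, colour = "red",
                        linetype = "twodash") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Mean of criterion and device",
                  y = sprintf("Difference (%s)",
                              gsub("_", " - ", ba$direction, fixed = TRUE)),
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Equivalence-zone plot
#'
#' Horizontal bars comparing the device estimates' 90% confidence interval
#' with the minimal equivalence zone around the criterion mean; vertical
#' dashed lines mark the zone bounds.
#'
#' @param eq A [minimal_equivalence_zone()] result.
#' @return A ggplot object.
#' @export
plot_equivalence <- function(eq) {
  stopifnot(inherits(eq, "equivalence_result"))
  df <- data.frame(
    what = factor(c("Device 90% CI", "Equivalence zone"),
                  levels = c("Equivalence zone", "Device 90% CI")),
    lo = c(eq$device_ci90[1], eq$ez_bounds[1]),
    hi = c(eq$device_ci90[2], eq$ez_bounds[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$what)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.25) +
    ggplot2::geom_vline(xintercept = eq$ez_bounds, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = eq$criterion_mean, colour = "grey40") +
    ggplot2::labs(x = "Estimate", y = NULL,
                  title = sprintf("Minimal equivalence zone: +/-%.1f%%",
                                  eq$ez_pct)) +
    ggplot2::theme_minimal()
}
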