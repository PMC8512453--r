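#' Simulate a black-box device summary from ground truth
#'
#' Models the consumer device as a biased, noisy reader of the true
#' quantities: `device = max(0, truth * (1 + bias) + offset + N(0, sd))`,
#' applied independently to MVPA minutes and active kilocalories with the
#' corresponding `device_*` parameters. With bias, offset, and sd all zero
#' the device reproduces truth exactly. Deterministic given
#' `params$seed` and the truth record's `subject_id`.
#'
#' @param truth A `truth_record` (see [lab_protocol_truth()]) or any list
#'   with `subject_id`, `true_mvpa` (min) and optionally `true_net_aee`
#'   (kcal); vectors give per-day summaries.
#' @param params A [sim_params()] object.
#' @return A `data.frame` with columns `subject_id`, `mvpa_min` and (when
#'   truth carries AEE) `aee_kcal`, one row per truth element.
#' @export
#' @examples
#' tr <- list(subject_id = "S1", true_mvpa = 20, true_net_aee = 100)
#' simulate_device_summary(tr, sim_params(device_mvpa_sd = 0,
#'                                        device_aee_sd = 0))
simulate_device_summary <- function(truth, params = sim_params()) {
  stopifnot(is.list(truth), !is.null(truth$subject_id),
            !is.null(truth$true_mvpa))
  if (!all(is.finite(truth$true_mvpa))) {
    stop("`true_mvpa` must be finite", call. = FALSE)
  }
  n <- length(truth$true_mvpa)
  with_seed(split_seed(params$seed, paste0("device:", truth$subject_id)), {
    mvpa <- pmax(0, truth$true_mvpa * (1 + params$device_mvpa_bias) +
                   params$device_mvpa_offset +
                   rnorm(n, 0, params$device_mvpa_sd))
    out <- data.frame(subject_id = truth$subject_id, mvpa_min = mvpa)
    if (!is.null(truth$true_net_aee)) {
      if (!all(is.finite(truth$true_net_aee))) {
        stop("`true_net_aee` must be finite", call. = FALSE)
      }
      out$aee_kcal <- pmax(0, truth$true_net_aee *
                             (1 + params$device_aee_bias) +
                             params$device_aee_offset +
                             rnorm(n, 0, params$device_aee_sd))
    }
    out
  })
}
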