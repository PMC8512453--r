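#' Simulation parameters for the synthetic-data generator
#'
#' Collects every tunable knob of the generator in one validated object.
#' Defaults describe a plausible child cohort wearing the devices under the
#' study's conditions; set the noise and bias parameters to zero for exact
#' round-trip checks.
#'
#' @param breath_interval_mean Mean breath spacing in seconds (children at
#'   mixed activity breathe roughly every 2-4 s). Must lie in (0.5, 10).
#' @param vo2_noise_cv Coefficient of variation of multiplicative
#'   breath-to-breath VO2 noise (dimensionless); 0 disables noise.
#' @param onkinetics_tau Time constant (s) of the first-order exponential
#'   transition of oxygen uptake between segment MET targets; 0 gives
#'   instantaneous steps.
#' @param resting_vo2_per_kg Resting oxygen uptake in mL/kg/min used as the
#'   simulated 1-MET rate. Children's resting VO2 exceeds the adult
#'   3.5 mL/kg/min convention, hence the default of 5.
#' @param accel_noise_floor Half-width (milli-g) of the uniform per-axis
#'   sensor noise added to the gravity vector during non-wear; 0 gives a
#'   pure unit-norm gravity signal.
#' @param accel_enmo_cv Coefficient of variation of the per-sample movement
#'   magnitude about a worn segment's target ENMO; 0 makes every sample's
#'   ENMO equal the target exactly.
#' @param met_to_enmo_slope,met_to_enmo_intercept Affine map from MET to
#'   expected epoch ENMO, `enmo_mg = intercept + slope * (met - 1)`, floored
#'   at zero. The defaults anchor the map to the Hildebrand children's
#'   wrist cut-points: 1.5 MET maps to 35.6 mg (sedentary threshold) and
#'   3.0 MET to 201.4 mg (moderate threshold), i.e. slope
#'   `(201.4 - 35.6)/1.5` mg/MET.
#' @param device_mvpa_bias,device_aee_bias Proportional device bias; the
#'   device reports `truth * (1 + bias)` before noise.
#' @param device_mvpa_sd,device_aee_sd Additive Gaussian device noise SD,
#'   in minutes and kcal respectively. Defaults of 2 min and 10 kcal are
#'   modest consumer-device noise levels.
#' @param device_mvpa_offset,device_aee_offset Additive device offset
#'   (minutes, kcal) applied after the proportional bias, e.g. a constant
#'   daily inflation; default 0.
#' @param seed Non-negative integer; the single global seed from which all
#'   stream seeds are derived via [split_seed()].
#' @return A list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(seed = 7, vo2_noise_cv = 0)
#' p$resting_vo2_per_kg
sim_params <- function(breath_interval_mean = 3,
                       vo2_noise_cv = 0.08,
                       onkinetics_tau = 20,
                       resting_vo2_per_kg = 5,
                       accel_noise_floor = 2,
                       accel_enmo_cv = 0.5,
                       met_to_enmo_slope = (201.4 - 35.6) / 1.5,
                       met_to_enmo_intercept = 35.6 - (201.4 - 35.6) / 3,
                       device_mvpa_bias = 0,
                       device_mvpa_sd = 2,
                       device_mvpa_offset = 0,
                       device_aee_bias = 0,
                       device_aee_sd = 10,
                       device_aee_offset = 0,
                       seed = 1L) {
  stop_if_not_scalar_number(breath_interval_mean, "breath_interval_mean",
                            min = 0.5, max = 10,
                            closed_min = FALSE, closed_max = FALSE)
  for (nm in c("vo2_noise_cv", "onkinetics_tau", "resting_vo2_per_kg",
               "accel_noise_floor", "accel_enmo_cv", "met_to_enmo_slope",
               "device_mvpa_sd", "device_aee_sd")) {
    stop_if_not_scalar_number(get(nm), nm, min = 0)
  }
  for (nm in c("met_to_enmo_intercept", "device_mvpa_bias",
               "device_mvpa_offset", "device_aee_bias",
               "device_aee_offset")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  stop_if_not_scalar_number(seed, "seed", min = 0)
  structure(list(
    breath_interval_mean = breath_interval_mean,
    vo2_noise_cv = vo2_noise_cv,
    onkinetics_tau = onkinetics_tau,
    resting_vo2_per_kg = resting_vo2_per_kg,
    accel_noise_floor = accel_noise_floor,
    accel_enmo_cv = accel_enmo_cv,
    met_to_enmo_slope = met_to_enmo_slope,
    met_to_enmo_intercept = met_to_enmo_intercept,
    device_mvpa_bias = device_mvpa_bias,
    device_mvpa_sd = device_mvpa_sd,
    device_mvpa_offset = device_mvpa_offset,
    device_aee_bias = device_aee_bias,
    device_aee_sd = device_aee_sd,
    device_aee_offset = device_aee_offset,
    seed = as.integer(seed)
  ), class = "sim_params")
}

# Expected epoch ENMO (mg) for a MET target under the affine map, floored
# at zero; non-wear (NA met) maps to 0.
met_to_enmo <- function(met, params) {
  e <- params$met_to_enmo_intercept + params$met_to_enmo_slope * (met - 1)
  e[is.na(met)] <- 0
  pmax(0, e)
}
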