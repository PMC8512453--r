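---
title: "Validating wrist-device MVPA and energy expenditure in children: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating wrist-device MVPA and energy expenditure in children: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watchval)
```

## The problem

Consumer wrist devices report two quantities that matter for paediatric
physical-activity research: minutes of moderate-to-vigorous physical
activity (MVPA) and active energy expenditure (AEE). Whether those numbers
can be trusted in school-aged children has to be established against
criterion instruments. `watchval` implements the two standard criterion
arms and the agreement statistics used to compare a device against them:

* **Laboratory arm** — breath-by-breath indirect calorimetry during a
  structured activity session. Oxygen uptake is converted to METs relative
  to the child's own measured resting rate, intensity is classified per
  epoch, and energy above basal metabolism is accumulated over the active
  stations.
* **Free-living arm** — raw 30 Hz wrist acceleration over about a week.
  The signal is calibrated, summarized as per-minute ENMO, classified with
  published cut-points, cleaned of non-wear algorithmically and by
  parent-reported logs, and aggregated to daily MVPA.

Because raw recordings from device-validation studies are rarely
deposited, the package also ships a synthetic-data generator with known
ground truth for every signal it consumes. All statements in this vignette
about what the pipelines recover are properties the test suite computes.

## The laboratory model

A session is a segment table ([`make_lab_protocol()`]): 3 min of inclined
rest, then 14 activity stations each preceded by a 1-min transition, 50
min in total at the defaults. Station MET targets span sedentary (1.3,
1.4), light (2.0–2.8), moderate (3.5–5.5), and vigorous (6.5, 7.5)
intensities; the identities and durations of the stations are a design
choice of this package (the station set of such protocols is conventional,
not canonical), with whole-minute durations so segment boundaries align
with 60-s epochs.

Processing follows five steps:

1. **Epoching** ([`aggregate_breaths()`]). Each breath reports the average
   uptake rate over its own interval; the series is a step function whose
   time-weighted mean is taken over each 60-s epoch. A breath's interval
   is capped at `max_gap = 30` s so dropouts become missing epochs rather
   than back-filled values; missing epochs are excluded from every mean
   and sum, never imputed as zero. The epoch length and breath-binning
   scheme of calorimetry processing are rarely reported in validation
   studies, so a time-weighted 60-s scheme matching the accelerometry
   arm's per-minute convention was adopted.
2. **Individualized 1-MET** ([`compute_resting_met()`]). The mean VO2 per
   kg over all complete rest epochs defines 1 MET. Children's resting
   uptake exceeds the adult 3.5 mL/kg/min convention, which is why the
   simulator defaults to 5 mL/kg/min and the pipeline never assumes 3.5.
   All rest epochs are used, including the first (no acclimation discard).
3. **Classification** ([`classify_met_intensity()`]). The published bands
   (SED at or below 1.5 MET, light 1.6–2.9, moderate 3.0–5.9, vigorous at
   or above 6.0) leave the open intervals (1.5, 1.6) and (5.9, 6.0)
   undefined for continuous METs. The package closes them half-open —
   SED ≤ 1.5 < LPA < 3.0 ≤ MPA < 6.0 ≤ VPA — preserving the printed
   anchors while partitioning the line.
4. **MVPA minutes** ([`mvpa_minutes()`]). Moderate-or-vigorous epochs
   times the epoch length, excluding transitions. Epochs straddling a
   segment boundary belong to the segment covering the majority of the
   epoch, ties to the earlier segment.
5. **Net AEE** ([`gross_active_aee()`], [`schofield_bmr()`],
   [`net_aee()`]). Over activity-station epochs only (rest, sedentary
   stations, and transitions removed), per-epoch kilocalories are
   `vo2 [L/min] × 4.867 kcal/L × minutes`. One unit note: the source
   description of this step says the mL/min signal is *multiplied* by
   1000 to obtain L/min; dimensionally that must be a division, and the
   package divides. Basal energy is Schofield's weight-only prediction
   (sex and age band 3–10 / 10–18 y), divided by 1440 min/day and
   multiplied by the active minutes, then subtracted. A negative net AEE
   is reported with a warning, not clamped.

## The free-living model

Raw tri-axial samples are calibrated with a simplified offset-plus-gain
least-squares fit ([`autocalibrate()`]): stationary 10-s windows (per-axis
SD < 13 mg) are regressed iteratively onto their closest points on the
unit gravity sphere. With fewer than three distinct stationary
orientations the model is unidentifiable and an identity fit is returned
flagged `converged = FALSE`. Temperature terms of full calibration
routines are out of scope.

ENMO is `max(0, ||a|| − 1)` per sample, truncated **before** averaging
into minutes (truncation after averaging would cancel sub-gravity against
supra-gravity samples; the tests pin a case where the two differ by
250 mg). Minutes are classified with the Hildebrand children's wrist
thresholds (35.6 / 201.4 / 707.0 mg), shipped as a named configuration
([`cut_points()`]) because thresholds are data, not logic.

Non-wear uses the Choi run-length rule on per-minute values
([`detect_nonwear()`]): at least 90 min of zeros, tolerating interruptions
of at most 2 consecutive non-zero minutes when flanked by at least 30 min
of zeros on both sides. The rule was defined on activity counts; applied
to ENMO, "zero" means below 1 mg (configurable). Parent-reported sleep
and non-wear intervals are excluded in addition ([`apply_logs()`]); since
the study description is ambiguous about whether sleep was removed by
algorithm, by log, or both, both paths are implemented and both applied by
default. Days retain at least 600 wear minutes (a convention of this
package; no published rule was stated) and daily MVPA is averaged over
retained days.

## Agreement and equivalence statistics

For paired participant values the package computes

* **MAPE** `mean(|criterion − device| / criterion) × 100`, participants
  (not epochs) being the unit of averaging;
* **mean bias** with a paired t test. The sign convention is explicit in
  every call: the lab arm defaults to criterion − device and the
  free-living arm to device − criterion, mirroring how such results are
  conventionally tabulated (a device that over-reads shows a positive
  free-living bias);
* **Bland–Altman** limits of agreement `bias ± 1.96 sd(differences)` and
  the 95% t interval of the bias; systematic bias is flagged when that
  interval excludes the line of equality;
* **minimal equivalence zone** ([`minimal_equivalence_zone()`]): the 90%
  t-interval of the device estimates is compared with a symmetric percent
  band around the criterion mean, and the *narrowest* band containing the
  interval is reported: `ez = 100 × max(mean − lo, hi − mean)/mean`.
  Instead of testing against a pre-registered zone (none is accepted for
  consumer devices), the statistic reports how wide the zone must be.

Numerical choices: `ez` is kept at full precision internally and rounded
to one decimal for reporting; the zone bounds are computed from the exact
value, so interval inclusion holds by construction and shrinking the zone
by one reporting unit (0.1) breaks it — a property the tests check
against a grid-search oracle. The 90% interval uses the t distribution;
published worked examples of this statistic are not always exactly
reproducible from printed summary rows (printed CIs may be asymmetric
about printed means, and a zone reported as 20.8% arises where the direct
formula on the printed numbers gives 20.70%, i.e. rounded upward at the
reporting grid); the package treats printed CI endpoints as inputs where
they are given and does not force agreement.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions: 20 lab subjects (ages
N(9.7, 1.9²) y truncated to [7, 13], heights and weights age-linked), a
50-min protocol, a 5-child free-living subsample wearing the devices for
7 days at 30 Hz with a programmed mean daily MVPA of 53.3 min.

* **Gas exchange**: breath spacing is gamma-distributed (mean 3 s, CV
  25%); expected uptake follows the segment MET target with first-order
  on-kinetics (τ = 20 s by default; τ = 0 gives exact steps) and mean-1
  lognormal noise (CV 8%). Breath intervals restart at segment
  boundaries, so a breath never spans two segments — this is what makes
  noiseless round trips exact rather than approximate.
* **Acceleration**: a worn segment's expected epoch ENMO follows an
  affine MET map anchored to the Hildebrand thresholds (1.5 MET → 35.6
  mg, 3.0 MET → 201.4 mg); only monotonicity of this map matters for the
  pipeline, not its physical fidelity. Non-wear is a fixed gravity vector
  plus bounded sensor noise (±2 mg per axis), which keeps non-wear epoch
  ENMO safely below the 1 mg Choi zero threshold.
* **Device**: a black box reading truth with proportional bias, additive
  offset, and Gaussian noise (`max(0, truth(1 + b) + o + ε)`). Defaults
  are unbiased with 2 min / 10 kcal noise.
* **Free-living days** are minute-aligned: nightly sleep (devices off), a
  95-min midday non-wear bout, morning and afternoon MVPA bouts, and
  light/sedentary filler, with every bout logged. Daily MVPA is realized
  in whole minutes — `round(days × 53.3)` minutes spread across days — so
  per-day truth is an integer; a requested mean of 53.3 min/day is
  realized as 373 minutes over 7 days (mean 53.29). Round-trip tests
  therefore assert exact recovery of the *scheduled* truth.

Not emulated: realistic gait frequency content (movement is magnitude
plus direction jitter, not an oscillatory waveform), heart rate,
altimetry, proprietary device containers, seasonal or weekend structure,
and behavioural intermittency within bouts. Passing round trips therefore
demonstrate that the pipelines are faithful to their definitions — not
that the device model matches any real device, nor that cut-point
classification is accurate on real children's movement.

Determinism: one global seed drives everything through a documented
splitting scheme ([`split_seed()`]), so identical configurations produce
identical reports and each module can be re-run independently.

## Worked example

```{r lab-example, eval = FALSE}
cfg <- run_config(seed = 1, n_subjects = 20)
report <- run_lab_validation(cfg)
report
```

The report prints, per metric, the criterion and device means (SD), MAPE,
the mean bias with its standard error, and the minimal equivalence zone;
`write_validation_report()` emits the same content as JSON, a summary
table, and Bland–Altman / equivalence figures.

## Problem sizes and test design

The test suite builds every fixture in code. Monte-Carlo checks use
10,000 subjects for the age distribution, 200 replicate gas-exchange
sessions for unbiasedness, 500 device draws for bias recovery, 10,000
replicates for 90% CI coverage, and 1,000 random 300-minute sequences for
the non-wear rule against a positionally coded brute-force oracle.
End-to-end recovery uses the study-sized cohorts (20 lab subjects; 5
free-living subjects over 7 days at 30 Hz, processed one day at a time so
memory stays flat). These sizes are the package's choices for stable yet
quick checks; all are parameters, not limits.

## Known limitations

* The calibration fit assumes offset and gain only; scale cross-talk and
  temperature drift are not modelled.
* Calendar days are local-midnight bounded with no time-zone or DST
  handling.
* The free-living equivalence comparison inherits whatever daily
  integer-resolution granularity the minute classification imposes.
* MAPE is undefined for zero criterion values and the package refuses to
  compute it then; studies with zero-MVPA participants need a different
  error metric.
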