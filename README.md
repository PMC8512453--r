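# watchval

Validation tooling for consumer wrist-device estimates of
moderate-to-vigorous physical activity (MVPA) and activity energy
expenditure (AEE) in school-aged children, against the two standard
criterion instruments:

* **breath-by-breath indirect calorimetry** in a structured lab session —
  oxygen uptake → individualized METs (1 MET = the child's own measured
  resting VO2 per kg) → intensity classes → MVPA minutes and net AEE
  above Schofield basal metabolism; and
* **raw 30 Hz wrist accelerometry** in free living — autocalibration →
  per-minute ENMO (`max(0, ‖a‖ − 1)` g, truncated per sample) →
  Hildebrand cut-point classes → Choi non-wear detection plus
  parent-reported wear logs → daily MVPA.

Agreement is quantified per metric with

* MAPE `= mean(|criterion − device| / criterion) × 100` over participants,
* mean bias (explicit sign convention) with a paired *t* test,
* Bland–Altman limits of agreement `bias ± 1.96 · sd(differences)` with a
  systematic-bias flag from the 95% CI of the bias, and
* the **minimal equivalence zone**: the narrowest symmetric percent band
  around the criterion mean that contains the device estimates' 90%
  *t*-interval, `ez = 100 · max(x̄c − lo, hi − x̄c) / x̄c`.

Because raw recordings from device-validation studies are rarely shared,
the package includes a first-class synthetic-data generator (subjects,
lab protocols, breath-by-breath gas exchange, 30 Hz tri-axial
acceleration, free-living weeks with logs, and a black-box device model)
with known ground truth, so both criterion arms and all statistics are
testable end to end. It is intended for methodologists designing or
auditing wearable-validation analyses, and as a reference implementation
of the processing rules themselves.

## Worked example

Simulate a 20-child lab cohort with the default (modestly noisy) device
model and validate it:

```r
library(watchval)
cfg <- run_config(seed = 1, n_subjects = 20)
report <- run_lab_validation(cfg)
report
#> <validation report: lab arm, n = 20>
#>   mvpa_min: criterion 16.8 (0.4), device 16.6 (1.3), MAPE 6.7%, bias 0.1 (SE 0.3), EZ +/-3.7%
#>   aee_kcal: criterion 55.4 (11.6), device 60.7 (17.3), MAPE 17.1%, bias -5.3 (SE 2.2), EZ +/-21.7%
```

Each line reads: criterion mean (SD) and device mean (SD) in the metric's
units (minutes, kcal); MAPE, the mean absolute percent error across
children; the mean bias (criterion − device in the lab arm) with its
standard error; and the minimal equivalence zone — e.g. the simulated
device's AEE estimates are only statistically equivalent to calorimetry
within a ±21.7% band, while its MVPA estimates sit inside a ±3.7% band.

The equivalence statistic can also be applied directly to published
summary numbers. From a device 90% CI of (16.63, 23.36) min and a
criterion mean of 20.2 min:

```r
minimal_equivalence_zone(c(16.63, 23.36), 20.2)
#> <equivalence> criterion mean 20.20; device 90% CI (16.63, 23.36)
#>   minimal EZ +/-17.7% (16.63 to 23.77); CI within EZ: TRUE
```

`run_freeliving_validation()` does the analogous free-living comparison
(daily MVPA from raw acceleration vs the device's daily summaries), and
`write_validation_report()` emits JSON, summary tables, and
Bland–Altman/equivalence figures. See the methods vignette
(`vignettes/device-validation-methods.Rmd`) for the models, parameter
choices, and limitations.

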