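Package: watchval
Title: Validation of Consumer Wrist-Device Activity Metrics Against
    Criterion Measures in Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to assess how well a consumer wrist device estimates
    moderate-to-vigorous physical activity (MVPA) time and activity energy
    expenditure (AEE) in school-aged children against criterion measures:
    breath-by-breath indirect calorimetry in the laboratory and raw
    wrist accelerometry in free living. Implements individualized MET
    derivation from oxygen uptake with Schofield basal metabolic rate,
    ENMO-based intensity classification with Hildebrand cut-points, Choi
    non-wear detection with wear-log exclusion, agreement statistics
    (mean absolute percent error, mean bias, Bland-Altman limits of
    agreement), and a minimal relative equivalence-zone statistic, plus a
    synthetic-data generator producing gas-exchange records, 30 Hz
    tri-axial acceleration, device summaries, and wear logs with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
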