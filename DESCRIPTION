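Package: frscal
Title: Framingham Risk Score Transport, Recalibration and Validation in
    Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for applying a sex-specific Framingham coronary heart
    disease (CHD) risk equation to a new cohort at an arbitrary prediction
    horizon, recalibrating it to that cohort (original coefficients, cohort
    risk-factor means, Kaplan-Meier baseline survival), refitting it by Cox
    proportional-hazards regression with collapsed risk-factor categories,
    and evaluating discrimination (Harrell's C-index with bootstrap optimism
    correction) and calibration (a decile-based chi-square test adapted to
    censored survival data, with predicted-to-observed risk ratio tables).
    Includes a synthetic elderly-cohort generator with a known
    proportional-hazards event process so the full pipeline can be exercised
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
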