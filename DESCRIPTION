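Package: esiquant
Title: Structure-Free Quantification for Non-Targeted LC/ESI/HRMS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-quantification of compounds detected in non-targeted
    LC/ESI/HRMS screening without analytical standards or structural
    assignment. Response factors (slope of peak area versus molar
    concentration) are predicted from twelve chromatographic and mass
    spectrometric descriptors -- positive/negative mode peak-area ratios at
    three mobile-phase pH values, retention times and their pH shifts, m/z,
    sodium-adduct formation, negative-mode detectability and nominal-mass
    parity -- using per-condition random-forest regressors. Includes
    calibration-curve fitting with automatic linear-range selection, two
    formula-defined baselines (equal response factor and closest-eluting
    standard), a simplified linear model on the pH 8.0 area ratio,
    permutation variable importance, interpretive regression trees,
    fold-error evaluation metrics, multiplicative uncertainty propagation,
    and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
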