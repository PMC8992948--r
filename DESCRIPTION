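Package: adaptrt
Title: In-Silico Daily-Adaptive Proton Therapy Trials on Synthetic
    Pelvic Anatomies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates the dosimetric comparison of non-adaptive (NART)
    and daily-adaptive (DART) intensity-modulated proton therapy for
    high-risk prostate cancer as a self-contained in-silico trial:
    synthetic pelvic phantoms with calibrated daily anatomical variation,
    a simplified spot-scanning proton dose engine (water-equivalent path
    length ray tracing, analytic Bragg curves, Gaussian lateral spread,
    constant RBE 1.1), worst-case robust spot-weight optimization for two
    opposed lateral fields, per-fraction dose recalculation under both
    strategies, deformable dose accumulation through the generator's
    ground-truth deformation, and evaluation via DVH indices,
    clinical-goal achievement rates, 3-D gamma analysis, paired t-tests
    and McNemar tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
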