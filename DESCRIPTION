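Package: ctalign
Title: Landmark-Based Symmetric Alignment of Head CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated rigid alignment of head CT volumes from three bony
    landmarks (right cochlea, left cochlea, nasal bridge). Detects landmarks
    from binary label maps via center of mass, computes a composite
    yaw-pitch-roll rotation that places all three landmarks on one axial
    plane with the cochleas mirror-symmetric, and applies it with a single
    interpolation pass. Includes a synthetic skull-phantom generator with
    exactly known landmark positions for end-to-end validation, deviation
    metrics for skull-base and whole-head alignment, and the associated
    statistics (paired Wilcoxon signed-rank on absolute deviations,
    Shapiro-Wilk normality gate, ICC(1,k) interrater reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
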