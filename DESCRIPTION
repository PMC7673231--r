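Package: tonellipse
Title: Acoustic Assessment of Mandarin Lexical Tone Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the acoustic assessment of Mandarin lexical tone
    production from monosyllabic word recordings or precomputed pitch
    landmark tables. Implements autocorrelation fundamental-frequency (F0)
    tracking with automated octave-error repair, per-speaker semitone
    normalization against the tone-1 mean, two-standard-deviation tone
    ellipses (F0 onset x offset) and ellipsoids (onset x midpoint x offset),
    Monte-Carlo region-overlap estimation, per-contrast tone
    differentiability scores, hit-rate confusion matrices, and the
    associated group statistics (arcsine transformation, factorial and
    repeated-measures ANOVA, Pearson correlation, demographic linear
    models). A synthetic cohort generator produces normal-hearing-like and
    cochlear-implant-like tone productions so the full pipeline is testable
    without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
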