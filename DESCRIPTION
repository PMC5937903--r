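Package: carotscreen
Title: Proteome-Wide Screening for Plasma Protein Correlates of
    Circulating Carotenoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-protein random-intercept linear mixed models for
    multiplexed (iTRAQ-style) relative-abundance proteomics screened
    against plasma carotenoid concentrations. Provides a profile-REML
    fitter with Wald inference and best linear unbiased predictions of
    plex effects, within-plex median normalization and detection
    filtering, Storey q-value false discovery rate control, correlation
    summaries, a plex-structured synthetic data generator with known
    ground truth, and a reproducible simulate/screen pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
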