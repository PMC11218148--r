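Package: passclock
Title: Passage Clocks from CpG Methylation for Anti-Ageing Compound Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and applies DNA-methylation "passage clocks" for serially
    passaged primary cell cultures. Screens CpG probes whose beta values drift
    with cell passage by per-probe linear regression, fits a sparse
    elastic-net predictor of passage number, and reads out drug-induced
    deceleration of cell-population ageing as predicted-minus-actual passage.
    Includes probe-level quality filtering for methylation arrays, robust
    Z scoring of senescence-marker panels, population-doubling arithmetic,
    and a seeded simulator of drifting methylomes with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
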