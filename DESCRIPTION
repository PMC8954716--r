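Package: plascreen
Title: Placental Lesion Severity Scoring and Postpartum Cardiovascular Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking synoptic placental histopathology to postpartum
    cardiovascular screening after preeclampsia. Implements a configurable
    lesion severity scoring scheme with etiological category caps, the
    categorical lifetime cardiovascular risk calculator based on seven
    postpartum risk factors, two-by-two association statistics (odds ratios
    with Woolf confidence intervals, Pearson chi-square), multivariable
    logistic prediction models evaluated by ROC AUC, a synthetic cohort
    generator with known ground-truth association parameters, and an
    end-to-end pipeline producing reproducible reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
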