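Package: cytodose
Title: Low-Dose Cytogenetic Biodosimetry from mFISH and Telomere qFISH Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration of low-dose X-ray cytogenetic biomarkers from
    multicolor-FISH aberration scoring and telomere qFISH fluorescence data.
    Provides mPAINT-style aberration classification and minimal break
    counting, per-dose frequency tables with exact significance tests,
    maximum-likelihood dose-response fitting (linear, linear-quadratic,
    exponential-saturation and induced-repair hyper-radiosensitivity
    families), detection-threshold dose estimation with Monte-Carlo 95%
    upper confidence limits, telomere T/C ratio analysis, and a synthetic
    data generator emulating the scoring experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
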