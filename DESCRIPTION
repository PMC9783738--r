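Package: cyclemap
Title: Quantitative Menstrual Cycle Mapping from Daily Urinary Hormones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps a menstrual cycle from daily urinary hormone
    measurements taken with quantitative at-home lateral-flow tests.
    Detects the estrone-3-glucuronide (E1G) rise, luteinizing hormone (LH)
    surge episodes, and pregnanediol-3-glucuronide (PdG) rise; derives the
    fertile window and its decomposition; confirms ovulation; classifies
    ovulatory function over the implantation window; computes an Ovulation
    Score; and screens early-cycle follicle-stimulating hormone (FSH) for
    diminished ovarian reserve.  Also provides lateral-flow standard-curve
    calibration and quality-control statistics (percent CV, 3-SD acceptance
    bounds, pass-rate gates), a synthetic cycle simulator with cohort
    presets for validation, cohort-level summary statistics with t-based
    confidence intervals and group comparisons, and per-cycle reports in
    JSON, Markdown, and HTML.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
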