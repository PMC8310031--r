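Package: mosvkit
Title: Missed Opportunities for Simultaneous Vaccination from Household Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes missed opportunities for simultaneous vaccination (MOSV)
    from child-level vaccination-date records of the kind collected by
    household coverage surveys (DHS, MICS, EPI cluster surveys). From dated
    card entries it reconstructs vaccination visits, evaluates dose
    eligibility against a configurable national schedule (minimum ages,
    minimum intervals, optional maximum ages), detects MOSVs under both crude
    and valid-dose accounting, and summarises them as visit-based and
    child-based indicators, counterfactual achievable coverage, and
    time-to-correction distributions, with optional survey weighting and
    stratification. A synthetic cohort generator with a known ground-truth
    event table supports end-to-end testing without access to
    registration-gated survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
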