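Package: typetrail
Title: Smartphone Typing Dynamics, Mood and Digital Trail Making Test Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links passively collected smartphone keypress dynamics and weekly
    clinician-rated mood to serially administered digital Trail Making Test
    part B (dTMT-B) performance. Implements the keypress-to-test time-window
    assignment algorithm, inter-key-delay typing features with session
    filtering, backpropagation of weekly mood ratings, two-level
    (grand-mean/within-subject) centering, from-scratch maximum-likelihood
    Gaussian linear mixed models with random slopes and a
    regression-discontinuity practice term, forward-fitted model comparison by
    likelihood-ratio tests, variance-partition R-squared, cross-modality
    intraclass correlations and paired t-tests, and a deterministic synthetic
    cohort generator that inverts the analysis model for end-to-end testing
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
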