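Package: lymphoval
Title: External Validation of Radiation-Induced Lymphopenia Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for externally validating published logistic risk models
    for severe radiation-induced lymphopenia during concurrent
    chemoradiotherapy. Ships the Christie (grade >=3) and MDACC (grade 4)
    lymphopenia scoring rules, CTCAE v5 grading of absolute lymphocyte
    count nadirs, rank-based discrimination (c-statistic with bootstrap
    confidence intervals), calibration in risk tertiles, intercept
    recalibration-in-the-large, univariable logistic screens, an EQD2
    fractionation helper, and a synthetic cohort generator (Gaussian
    copula over log-normal and truncated-normal marginals with declining
    lymphocyte trajectories) so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
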