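Package: ofaffcea
Title: Cost-Effectiveness Analysis of Omental Fat-Augmented Free Flap Breast Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing omental
    fat-augmented free flap (O-FAFF), abdominal free flap, and implant-based
    breast reconstruction after mastectomy. Implements a monthly-cycle Markov
    state-transition model evaluated both by deterministic cohort expectation
    and by patient-level Monte Carlo microsimulation, producing discounted
    costs and breast quality-adjusted life-years (B-QALYs), incremental
    cost-effectiveness ratios with dominance classification, one-way
    deterministic (tornado) sensitivity analyses, and probabilistic
    sensitivity analyses with cost-effectiveness acceptability curves.
    Because the study's institutional transition probabilities are not
    published, a calibration module derives per-arm event rates and state
    utility weights from the published aggregate cost, utility, and
    incremental tables, and a synthetic Gompertz life-table generator stands
    in for national all-cause mortality data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
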