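Package: threatlearn
Title: Computational Modeling of Threat Conditioning and Extinction from
    Skin-Conductance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-level analysis pipeline for Pavlovian threat conditioning
    and extinction indexed by skin-conductance responses (SCR). Provides a
    family of fourteen associative-learning model variants (Rescorla-Wagner
    with learning inertia, Bayesian learning-rate decay and response
    habituation; Rescorla-Wagner/Pearce-Hall hybrids with regression
    read-outs; Beta-Bernoulli uncertainty models), per-subject least-squares
    fitting with multi-start simplex search, BIC-based model comparison,
    parameter- and model-recovery simulation, SCR cleaning rules
    (interpolation, extrapolation, outlier and missingness exclusion), and
    association analyses linking fitted learning parameters to anxiety
    severity, age, and subcortical gray-matter volume with permutation-based
    family-wise error control. A synthetic-cohort generator emulates the
    conditioning task schedule and the statistical structure the analyses
    assume, so the full pipeline is testable without access to participant
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
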