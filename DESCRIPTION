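Package: cogtrainr
Title: Adaptive Scheduling, Scoring, and Adherence Monitoring for
    Computerized Cognitive Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An engine for delivering multidomain computerized cognitive
    training (CCT). Builds a per-participant cognitive profile from
    standardized baseline test scores across seven cognitive domains,
    composes 17-exercise "sandwich" training sessions that interleave
    easy (strength-domain), medium, and hard (weakness-domain) exercises
    in fixed positions, refreshes the profile from within-training
    performance at prescribed session boundaries, converts raw exercise
    results into cohort-comparable scores with a top-quartile feedback
    target zone, and monitors adherence with rule-based red/orange flags,
    escalation, a trainer ticket lifecycle, throttled notifications, and
    CheerSquad milestone events. A seeded virtual-participant simulator
    generates normative cohorts and complete synthetic training modules
    so every component can be exercised without trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
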