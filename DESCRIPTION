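Package: foragesim
Title: Simulation and Analysis of Continuous Three-Patch Foraging Under
    Variable-Interval Reward Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generative models and analysis tools for continuous foraging
    experiments in which a subject harvests three reward patches governed by
    concurrent variable-interval schedules. Supports memoryless (exponential)
    and increasing-hazard (gamma, shape 10) reward-availability intervals,
    dynamic scale-invariant (1/f) texture stimuli carrying a phase-encoded
    availability cue whose reliability is set by a concentration parameter,
    heuristic forager agents that produce realistic push-event logs, and the
    full behavioral analysis pipeline: push-fraction matching statistics,
    inter-push-interval summaries, patch-transition matrices, visit
    segmentation with rate-matched null-model normalization of stay and
    return times, continuous push rate, and time-resolved allocation
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    png,
    optparse
Config/testthat/edition: 3
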