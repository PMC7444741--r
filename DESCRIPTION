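Package: activeinf
Title: Active Inference Simulation of a Rule-Cued Cross-Modal Delayed
    Attention Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-state active-inference (POMDP) simulator of a rodent
    delayed cross-modal attention task. An auditory cue instructs an
    attentional rule (attend vision or attend audition); after a delay,
    conflicting visual and auditory targets are presented and the agent must
    report the target indicated by the cued modality. The package builds the
    categorical generative model (likelihood, transition, preference and
    prior arrays), performs variational message passing with expected
    free-energy policy selection, simulates delay-period firing rates and
    local field potentials from the belief dynamics, reproduces in-silico
    lateral and medial prefrontal lesions, and provides a canonical variates
    analysis for relating simulated population activity to synthetic
    multivariate neural data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
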