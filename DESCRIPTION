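Package: attnvalue
Title: Pseudo-Population Decoding of Covert Attention and Partial-Determination Analysis of Value Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing prefrontal spiking data recorded in a
    reward-salience Posner cueing task: a synthetic task-and-spike-train
    generator (trial schedules with truncated-exponential change latencies,
    behavioural outcomes, inhomogeneous Poisson populations with
    configurable cue- and value-coding structure), behavioural scoring and
    across-session paired comparisons, pseudo-population linear discriminant
    decoding of the attention cue location with cross-temporal
    generalization and shuffle/FDR significance, and coefficient-of-partial-
    determination (CPD) quantification of salient-value versus cued-value
    coding in single neurons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
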