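Package: forcejump
Title: Force-Jump Optical Tweezers Analysis and Catch-Bond Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule force-jump optical
    tweezers assays that read out protein-protein bond rupture as a
    position step on a DNA tether. Implements the worm-like-chain
    mechanical circuit that partitions trap force between a
    protein-bearing loading strand and a single-stranded DNA bridge,
    two-state one-way hidden Markov (Viterbi) changepoint detection of
    rupture events in constant-force plateaus, dwell-time survival
    analysis with single-exponential fits, two-pathway ("catch-slip")
    Bell-model fitting of mean bond lifetime versus load with critical
    force extraction, and single-site binding isotherm fits for
    thermophoresis titrations. A synthetic-data module simulates
    complete force-jump sessions and titrations with known ground truth
    so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
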