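Package: bayesgaze
Title: Bayesian Reasoning Strategies and Gaze Analytics for Two-Event Statistical Situations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how people reason about statistical situations built
    from two binary events (disease x test result, course choice x career orientation).
    Derives all sixteen probabilities and the natural-frequency tree of a scenario,
    predicts the answers produced by the correct Bayesian strategy and by the cataloged
    erroneous strategies (joint occurrence, Fisherian, pre-Bayes, likelihood
    subtraction/addition, and others), and classifies observed answers against them.
    Includes area-of-interest (AOI) eye-tracking descriptives (dwell time, fixation
    counts, hit ratios, scan-path order, duration-weighted heat maps) for tree-diagram
    and 2x2-table stimuli, and a seeded simulator of the full 24-participant,
    20-inference experimental design that generates strategy-conditioned answers and
    fixation sequences for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
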