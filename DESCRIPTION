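Package: srtkit
Title: Construction and Simulation of Adaptive Speech-in-Noise Sentence Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and validating adaptive sentence-in-noise
    speech tests: psychometric filtering of a sentence corpus,
    intelligibility normalization via per-sentence level offsets,
    cost-minimizing assignment of sentences into equivalent test lists, a
    three-phase adaptive speech-reception-threshold (SRT) staircase, a
    Monte Carlo virtual-listener simulator of complete normative studies,
    and the validation statistics (list equivalence, within-subject
    variability, post hoc psychometric slopes, and a linear mixed-effects
    training-effect analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
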