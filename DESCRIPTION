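Package: turntaking
Title: Turn-Taking Analysis of Cooperative Offspring Provisioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify turn-taking in cooperative offspring
    provisioning from timestamped nest-visit records. Collapses raw
    PIT-tag reads into visits, identifies significant carers by an
    iterative visit-count rule, fits continuous-time Markov models of
    who-follows-whom at the nest (full, per-individual, and pooled rate
    structures) with likelihood-ratio comparisons, computes sequence
    alternation statistics (k-category and Wald-Wolfowitz runs tests),
    and separates "active" turn-taking (carers responding to one
    another) from "passive" turn-taking (group-size, rate-inequality,
    and refractory-period artifacts) via a within-carer inter-visit
    interval randomization test. Includes a mechanistic provisioning
    simulator with refractory periods and response rules for power and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
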