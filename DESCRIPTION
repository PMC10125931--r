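Package: satscores
Title: Combined Speed-Accuracy Performance Scores with Diffusion-Model
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes combined performance measures that integrate mean
    response time and accuracy for behavioral experiments: the Balanced
    Integration Score (BIS, including an RT-scaled variant), the Linear
    Integrated Speed-Accuracy Score (LISAS, including condition-wise and
    aggregated-SD variants), the Inverse Efficiency Score and the Rate
    Correct Score.  Ships a two-boundary Wiener diffusion simulator with
    closed-form first-passage oracles, a generator for two-condition
    within-participants designs with explicit between- and
    within-participant variance components, and a Monte-Carlo study
    harness (paired t tests, d_z effect sizes, percent significant,
    between-condition correlations) for checking how each measure reacts
    to genuine difficulty effects versus speed-accuracy trade-offs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
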