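Package: targetmr
Title: Drug-Target Mendelian Randomization with Mediation Through
    Molecular Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization toolkit for drug-target
    analyses. Selects cis instruments around drug-target genes with an
    adaptive LD-clumping rule, harmonizes exposure and outcome summary
    statistics, and estimates causal effects by inverse-variance
    weighting, MR-Egger regression and the weighted median with a
    parametric bootstrap. Ships the standard sensitivity battery
    (Cochran's Q, Egger intercept, leave-one-out, simulation-based
    global/outlier/distortion tests) and two-step mediation through
    circulating protein levels using the product-of-coefficients
    decomposition. A seeded summary-statistics simulator with known
    causal structure supports validation without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
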