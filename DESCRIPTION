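Package: lbptrial
Title: Microbiome and Mucosal-Immune Analysis of a Live-Biotherapeutic Vaginal Trial
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for randomized trials of a vaginal live
    biotherapeutic product (LBP). Implements constrained microbiome topic
    modeling (latent Dirichlet allocation on non-Lactobacillus counts with
    pure Lactobacillus topics and whole-community rescaling), topic alignment
    across resolutions for choosing the number of topics, swab size-effect
    adjustment of cytokine panels by first-principal-component subtraction
    with limit-of-quantification imputation, microbiota-immune association
    via the RV coefficient, PERMANOVA and DiSTATIS, Wald benefit ratios with
    Wilson stratum intervals and heterogeneity-of-treatment-effect tests,
    probiotic-strain versus native-strain transition dynamics, and multiblock
    PLS discriminant analysis with block importance. Includes a synthetic
    cohort generator emulating a 2:1-randomized longitudinal trial so the
    full pipeline can be exercised and validated without access to trial
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
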