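Package: gpmono
Title: Monotonicity of Genotype-Phenotype Maps from Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies order-preservation (monotonicity) of diploid
    genotype-phenotype maps with two measures: a substitution-effect degree
    of monotonicity and an isotonic-regression decomposition into monotone
    and non-monotone components. Decomposes maps into additive, dominance
    and epistatic variance components under equal genotype frequencies
    (unweighted-regression NOIA formulation). Generates genotype-phenotype
    maps from diploid sigmoid gene-regulatory-network ODE models,
    enumerates the full 3-gene motif space and classifies motifs by
    feedback and feedforward loop content to relate regulatory
    architecture to non-monotonicity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    withr,
    optparse
Config/testthat/edition: 3
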