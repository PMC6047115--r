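Package: growthqtl
Title: Functional QTL Mapping of Longitudinal Plant Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Functional mapping of quantitative trait loci from longitudinal
    plant-phenomics data in multiparental (MAGIC) populations. Fits non-linear
    growth models (logistic, 4-parameter logistic, Gompertz) and a two-component
    Gaussian mixture to per-plant trait trajectories, decomposes fitted curve
    parameters into genetic and environmental variance components (heritability,
    genetic correlations), and scans markers for association with single-timepoint
    traits and curve parameters using one-way ANOVA with permutation-based
    genome-wide significance. Includes a MAGIC recombinant-inbred-line simulator
    that generates genotypes with known founder mosaics and trait trajectories
    with planted QTL effects, so every stage of the workflow can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
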