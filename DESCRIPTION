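Package: rvpower
Title: Power of Rare-Variant Association Tests Under Evolutionary
    Genetic Architectures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A simulation framework for studying the statistical power of
    rare-variant association tests (RVATs) when the genetic architecture of
    a complex trait is shaped by demography and purifying selection.
    Simulates neutral haplotype panels under a two-population out-of-Africa
    demographic history (through the msprime coalescent simulator), forward
    Wright-Fisher simulation of deleterious variants with a gamma
    distribution of fitness effects, the rho/tau mapping from selection
    coefficients to phenotypic effect sizes, quantitative-trait synthesis
    and case/control sampling designs (random, 50/50, phenotypic extremes),
    genotyping-array downsampling with haplotype-copying imputation, and
    from-scratch implementations of SKAT, SKAT-O, KBAC and single-variant
    logistic association, together with power, conditional-power,
    variance-partitioning (V_x) and discovery-window summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
SystemRequirements: Python (>= 3.8) with the msprime package on the
    executable search path (used as the coalescent simulation backend).
Config/testthat/edition: 3
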