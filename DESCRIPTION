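Package: germdiv
Title: Phenotypic and SSR-Based Genetic Characterization of Crop Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint phenotypic and molecular characterization of
    crop germplasm collections evaluated in replicated incomplete-block field
    trials and genotyped with SSR (microsatellite) markers. Fits per-trait
    random-genotype mixed models by REML to obtain variance components,
    broad-sense heritability, genetic coefficients of variation and BLUP
    genotype means; computes binned Shannon-Weaver phenotypic diversity,
    Pearson and partial trait correlations, PCA-based clustering with v-test
    cluster characterization, and the multi-trait genotype-ideotype distance
    (MGIDI) selection index. For marker data it provides per-locus diversity
    statistics (Na, Ne, I, Ho, He, PIC, discriminating power, private
    alleles), Jaccard dissimilarity with bootstrapped neighbor-joining trees,
    a Gibbs-sampler admixture model with Evanno Delta-K model choice,
    three-level AMOVA with permutation-tested F-statistics, and Nei
    distance/identity between inferred populations. A synthetic-panel
    generator with known ground truth (alpha-lattice trial layout, correlated
    traits with target heritabilities, Balding-Nichols population divergence)
    makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    ape,
    MASS,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
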