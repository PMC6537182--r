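Package: whogem
Title: Admixture-Based Geolocation and Quantitative Trait Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting where a plant or animal sample comes from,
    and what quantitative phenotypes it is likely to show, from its genome
    admixture proportions.  Implements supervised and unsupervised admixture
    estimation with a binomial-likelihood EM, cross-validation error curves
    and DAPC-style BIC scans for choosing the number of ancestral components,
    a provenance-prediction algorithm that converts admixture distances into
    geographic placements through an isolation-by-distance calibration,
    linear trait prediction from admixture proportions with best-minimum-model
    search, five standard genomic-selection baselines (RR-BLUP, G-BLUP,
    BayesB, RKHS, LASSO), repeated stratified cross-validation with
    Kruskal-Wallis method comparison, and redundancy-analysis variation
    partitioning of admixture against climate and geography.  A seeded
    landscape-genetics simulator (Balding-Nichols allele frequencies,
    distance-decay admixture on a map, Q-linear traits, spatially structured
    climate) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    data.table
Suggests:
    testthat (>= 3.0.0),
    vegan,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
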