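Package: snpBVS
Title: Bayesian Stochastic Variable Selection for Rare and Common Variant
    Association with Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spike-and-slab Bayesian variable selection regression for
    identifying rare and common variants associated with quantitative
    traits. Models all SNPs simultaneously with a Gibbs sampler using
    scaled inverse chi-square priors on the residual and slab variances,
    reports per-SNP posterior probabilities of association (PPA) and
    effect estimates, and evaluates variant ranking by replicate-averaged
    scores, ROC curves and AUC. Includes an exact model-enumeration
    oracle for validating the sampler on small problems and a mini-exome
    simulator producing genotype/phenotype replicate sets with known
    causal architecture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomicRanges,
    optparse,
    knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
biocViews: Bayesian, GenomeWideAssociationStudy, SNP, Regression,
    VariantDetection, Software
RoxygenNote: 7.3.3
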