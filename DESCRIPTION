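Package: igeblup
Title: Single-Step Genomic Evaluation with Indirect Genetic Effects for
    Group-Housed Animals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genetic evaluation of socially affected traits in
    group-housed livestock, such as average daily gain in pen-housed pigs.
    Implements pedigree validation, the numerator relationship matrix and
    its sparse inverse, SNP quality control, the VanRaden genomic
    relationship matrix, tuning and blending towards the pedigree
    relationships of genotyped animals, and the single-step (H) inverse.
    Fits animal models with direct genetic effects only or with both direct
    and indirect (social) genetic effects via Henderson's mixed-model
    equations, estimates variance components by average-information REML,
    and summarises direct and total heritability. Includes a forward
    (date-split) validation protocol with corrected phenotypes, predictive
    correlations, prediction bias, the Hotelling-Williams test for dependent
    correlations, and a sweep over the genomic blending weight. A synthetic
    herd generator (pedigree, gene-dropped genotypes, weight-based pen
    allocation, and phenotypes simulated under the indirect genetic model)
    makes every stage testable without access to proprietary herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
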