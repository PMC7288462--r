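Package: musselpop
Title: Population Structure, Hybrid Zones and Environmental Association
    for Blue Mussel SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for diploid SNP genotypes sampled from
    hybridizing blue mussel (Mytilus edulis, M. trossulus and
    M. galloprovincialis) populations.  Reads Genepop and wide-CSV
    genotype tables, computes per-population diversity statistics with
    exact Hardy-Weinberg tests and Benjamini-Yekutieli correction,
    Weir-Cockerham FST with permutation tests, an island-model FST
    outlier scan, phase-free genotypic linkage disequilibrium tests,
    neighbour-joining trees and correspondence analysis.  Detects
    hybrids through a diagnostic-SNP hybrid index, a six-category
    genotype-class posterior and supervised ancestry estimation, and
    links allele frequencies to local environmental gradients with an
    in-package boosted-regression-trees learner (Bernoulli and
    multinomial losses, cross-validated tree selection, relative
    influence, partial dependence), ANOSIM and SIMPER on Bray-Curtis
    dissimilarities, and abrupt-transition detection along clines.
    A seeded simulator generates multi-population three-taxon datasets
    with hybrid zones and environmental clines for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
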