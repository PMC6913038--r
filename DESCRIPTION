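Package: hsfinemap
Title: Haplotype-Based Fine Mapping of Fertility QTL in Half-Sib Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sires heterozygous for haploblock QTL from posterior
    contrasts of haplotype-allele effects estimated under a Bayes B mixture
    model, using a liability threshold model for binary fertility traits and
    a Gaussian model for continuous ones. Whole-genome sequence variants are
    then imputed onto chip haplotype fragments by ordinary least-squares
    regression, and variants concordant with each sire's QTL segregation
    status are retained under a single-QTN assumption, followed by gene
    assignment and hypergeometric over-representation analysis. A half-sib
    population simulator with planted causal variants supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
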