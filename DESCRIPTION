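Package: congenicQTL
Title: Dissection of Quantitative Trait Loci with Branching Congenic Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping a quantitative trait locus (QTL) with a
    panel of branching mouse congenic strains carrying donor-strain chromosomal
    fragments on an inbred host background. Provides donor-region interval
    algebra, flanking-marker genotype imputation under a no-double-recombination
    rule, phenotype preparation (exclusions, normality diagnosis with log
    transformation, covariate screening), a pooled general linear model marker
    scan with sequential (Type-1) sums of squares and Bonferroni-style
    thresholds, the common segment classification of strains, a minimum
    spanning tree ordered sequential strain comparison method that can resolve
    a single mapped locus into several linked QTLs with signed allelic effects,
    candidate-gene expression filtering, and a synthetic congenic panel
    generator for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
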