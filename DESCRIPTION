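Package: popsweep
Title: Selective-Sweep Mapping and F2 Fine-Mapping for Domestication Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage selective-sweep mapping pipeline for domestication
    studies: windowed Weir-Cockerham fixation index (FST) and nucleotide
    diversity (pi) ln-ratio scans with Z-test calling of candidate divergent
    regions (CDRs), fixed-site and standing-variation screens against an
    outgroup-polarized ancestral state, the ABBA-BABA D-statistic with a
    weighted block jackknife, and wild x domestic F2 intercross fine-mapping
    (diagnostic-marker selection, recombination-breakpoint haplotype
    classification, GLM phenotype adjustment, genotype-class effect and
    variance-explained estimation, segregation tests, junction-read structural
    variant genotyping, and 2^-ddCt relative expression). Includes a forward
    Wright-Fisher simulator with recombination, selection, bottlenecks and
    migration that emulates a wild / indigenous / elite population design plus
    an F2 cross, so the whole pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
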