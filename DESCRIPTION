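Package: endosirna
Title: Classification of Endogenous Small Interfering RNAs from Small-RNA
    Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for identifying and subclassifying endogenous small
    interfering RNAs (endo-siRNAs) from small-RNA sequencing libraries of
    gametes and early embryos. Reads are adapter-trimmed, length-filtered and
    collapsed into unique tags, placed on a reference genome by perfect-match
    alignment, and annotated in tiers as structural ncRNA, miRNA, piRNA or
    putative endo-siRNA. Endo-siRNA candidates are subclassified as
    transposable-element-derived (TE-siRNA), long-hairpin-derived (Lhp-siRNA,
    via genomic clustering and base-pair-maximization folding) or
    inverted-complement mRNA-derived (IC-siRNA). Stage-enriched tags are
    selected with a Fisher exact screen on counts-per-million, and a model of
    the LINE-1 antisense-promoter transcript locates upstream antisense
    homology to ORF2, constructs the sense-antisense dsRNA duplex and assigns
    L1-specific siRNAs to it. A synthetic-data module generates toy genomes
    with planted features and simulated stage libraries with ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
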