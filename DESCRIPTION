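Package: hspreg
Title: Regulatory-Region Differentiation and Basal Expression Analysis for
    hsp70 Chromosomal Arrangements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare cis-regulatory structure and basal mRNA
    expression of the hsp70 gene family between cold- and warm-climate
    chromosomal arrangements of Drosophila subobscura. Annotates heat-shock
    elements (HSEs), GAGA sites, TATA boxes and AU-rich elements on promoter
    and 3'UTR haplotype alignments; computes between-arrangement
    differentiation (site classification, Dxy, Hudson's Fst, Hudson's Snn
    with a label-permutation test); quantifies relative expression from qPCR
    Ct tables by the comparative CT (2^-dCT) method and fits a nested
    mixed-model ANOVA validated by a four-stage restricted permutation
    procedure. Includes seeded synthetic-data generators that emit haplotype
    alignments with planted motifs and site classes, and Ct datasets with
    known effects, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    seqinr,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
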