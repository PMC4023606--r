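Package: gcabias
Title: Combining Ability and Parental Bias Analysis for Diallel Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking general combining ability (GCA) of inbred
    parents to transcriptome and histone-modification bias in their F1
    hybrids. Implements Griffing's Method 2 and Method 4 fixed-effect
    estimators for half-diallel designs, RPKM quantification of gene and
    gene-body read counts, the Audic-Claverie two-library count test with
    Benjamini-Hochberg false discovery rate control, classification of F1
    expression relative to the two parents (equal to one parent, above or
    below both, or intermediate), parental-similarity and bias summaries,
    gene-body ChIP signal comparison between hybrids and parents, and
    correlation-based sample clustering. A synthetic-data module generates
    diallel phenotype tables, parent/hybrid count matrices, gene models and
    ChIP count tables with known ground truth so the whole pipeline can be
    validated without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    ape,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
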