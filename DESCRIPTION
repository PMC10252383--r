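Package: triopatterns
Title: Expression and Methylation Pattern Classification in Parent-Hybrid Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of small RNA, transcriptome and DNA
    methylome data from an F1 hybrid and its two inbred parents. Classifies
    features (miRNAs, siRNA clusters, genes) into five hybrid expression
    patterns from the dominance/additivity (D/A) ratio, classifies hybrid
    methylation of genomic regions into trans-chromosomal methylation
    (TCM), demethylation (TCdM) and non-interactive (NIM) patterns from the
    Met_d/a statistic on weighted methylation levels, annotates siRNA
    clusters to genomic features, joins the layers into expression-by-
    methylation pattern groups with association and enrichment tests, and
    computes mid-parent and better-parent heterosis from trait data. Ships
    a seeded synthetic-data generator with planted ground truth so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
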