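Package: ribofree
Title: Evaluation of rRNA Removal Efficiency in Bacterial RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well ribosomal RNA depletion protocols
    perform in bacterial RNA sequencing experiments. Reads are classified
    against a genome annotation into rRNA, mRNA (CDS) and intergenic
    categories; a detection threshold for significantly expressed genes is
    derived from a geometric null model of background read assignment;
    enrichment folds, detection-sensitivity gains and required sequencing
    depth are computed from the category statistics; and the robustness of
    mRNA relative abundance (log-RPKM correlation) and of differential
    expression profiles (size-factor normalised fold changes) is assessed.
    A synthetic-data generator emulating an rRNA-dominated bacterial
    library under configurable depletion-treatment models drives fully
    reproducible end-to-end analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
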