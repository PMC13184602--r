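Package: gbmeth
Title: Gene-Body Methylation Analysis for Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-alignment analysis of whole-genome bisulfite sequencing data
    from per-cytosine reports (Bismark CX dialect): read-depth filtering,
    classification of cytosines by sequence context (CpG, CHG, CHH), genomic
    region (exonic, intronic, intergenic) and methylation intensity
    (hypomethylated, intermediate, hypermethylated); gene-level exonic
    methylation aggregation; contrast statistics between conditions (median
    methylation shift, paired Wilcoxon signed-rank tests with
    Benjamini-Hochberg correction, differentially methylated gene calling,
    one-way ANOVA with Fisher's LSD letter groups); multivariate pattern
    discovery (PCA of most-variable features, hierarchical clustering of
    common hypermethylated genes, multi-set overlap counts); and a synthetic
    methylome generator with known ground truth so the whole pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
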