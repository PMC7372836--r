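Package: stemethyl
Title: Whole-Genome Bisulfite Sequencing Methylome Analysis for Developing Plant Stems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for plant whole-genome bisulfite
    sequencing (WGBS) methylomes. Starting from per-cytosine methylation call
    tables, the package estimates bisulfite conversion rates from an
    unmethylated lambda spike-in, calls methylated cytosines with a binomial
    test against the non-conversion null, merges biological replicates in
    200 bp sliding windows (100 bp step), detects differentially methylated
    regions (DMRs) per sequence context (CG, CHG, CHH) with Pearson's
    chi-square test and context-specific coverage and effect-size criteria,
    annotates differentially methylated genes (DMGs), computes genomic-feature
    methylation profiles (gene bodies, promoters, UTRs, exons, introns,
    transposable elements and their flanks), and integrates methylation with
    gene expression (FPKM bins, methylation tertiles, Spearman correlation,
    DMG/DEG intersection). A fully seeded synthetic-study generator produces
    genomes, annotations, spike-ins, call tables and expression tables with
    known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
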