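Package: methbin
Title: Bin-Based Differential Methylation Analysis for Whole-Genome
    Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling differentially methylated regions (DMRs)
    from per-cytosine whole-genome bisulfite sequencing call tables in
    100-bp genomic bins, separately in the CG, CHG and CHH sequence
    contexts, using a two-sided Fisher exact test on pooled counts with
    Benjamini-Hochberg false discovery rate control and context-specific
    effect-size thresholds. Includes multi-replicate DMR conservation by
    direct N-way interval intersection and by clustering-based concordance
    selection ("relaxed" DMRs), interval merging into loci, annotation
    overlap filtering, browser-track export, targeted quantification of
    regions from call tables or clone-based bisulfite alignments, and
    McrBC-qPCR relative methylation. A seeded synthetic methylome
    generator emulates compartmentalised plant methylomes with planted
    DMRs, replicate-private hypervariable regions, Poisson coverage and
    incomplete bisulfite conversion, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
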