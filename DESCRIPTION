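Package: svmatchr
Title: Structural Variant Comparison, Benchmarking and Merging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise comparison of sequence-resolved structural variants (SVs)
    from sorted VCF files. Implements reference-distance, reciprocal-overlap,
    size-similarity and haplotype sequence-similarity metrics, TruScore-ranked
    match assignment, truth-set benchmarking with precision/recall/F1 and
    genotype concordance, redundancy-aware merging (collapse) with genotype
    consolidation, neighborhood and breakpoint-interval annotation, a
    tandem-repeat redundant/missing merge audit, and a deterministic synthetic
    fixture generator (references, implanted truth callsets, perturbed
    replicates, multi-sample cohorts and tandem-repeat loci).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
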