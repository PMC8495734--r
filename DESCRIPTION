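Package: canprofiler
Title: Genotype-Specific Mutation Profiles from Pooled Reporter-Gene Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds background-filtered, genotype-specific mutation profiles
    from targeted deep sequencing of a selectable reporter locus (the yeast
    CAN1 arginine permease). Takes per-sample low-frequency variant calls
    (VCF) over pooled canavanine-resistant colonies, classifies variants
    (strand-collapsed SNV classes, single-base and complex in/dels, MNVs,
    replacements), learns an empirical background filter from permissive
    (unselected) control pools (global frequency floor plus position-specific
    maxima), and aggregates filtered replicates into per-genotype profiles:
    unique counts, summed and averaged frequencies, high-frequency and
    jackpot variants, 96-category trinucleotide-context spectra normalised by
    reference triplet occurrence, replicate-fraction hierarchical clustering
    and per-class motif models. Includes a pooled-colony experiment simulator
    with known ground truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
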