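Package: rrnabias
Title: Simulation and Bias Assessment of 16S rRNA Microbiome Profiling Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare the three common 16S-rRNA-based strategies for
    profiling a prokaryotic community -- V4 amplicon sequencing, shotgun DNA
    (metagenomic) sequencing and shotgun RNA (metatranscriptomic) sequencing --
    and to dissect the biases specific to each. The package generates synthetic
    reference communities with realistic 16S architecture (alternating conserved
    and hypervariable blocks, per-taxon rRNA operon copy numbers, per-cell
    expression rates, and engineered primer-site mismatches), simulates
    paired-end reads under the weighting law of each strategy, and implements
    the analysis chain used in comparative microbiome studies: sliding-window
    quality filtering, alignment-based rRNA read selection, overlap-based
    paired-end merging, naive Bayes k-mer taxonomic classification with
    bootstrap confidence, forward/reverse concordance merging, hypervariable
    region binning, in-silico PCR with degenerate primers, rarefaction of taxon
    discovery, and cross-method abundance comparison with log2 ratios and
    replicate-level differential abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    Matrix,
    methods,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
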