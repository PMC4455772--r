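Package: crossmeth
Title: Cross-Species Transfer and Validation of Infinium 450K Methylation Probes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Aligns human Infinium HumanMethylation450 probe sequences to a
    non-human genome with seed-and-extend local alignment and Karlin-Altschul
    bitscore/e-value statistics, classifies probe-genome mismatches by their
    position relative to the assayed CpG, applies a three-step probe filter
    (bitscore, uniqueness, no mismatch at or adjacent to the CpG), reconciles
    human gene annotation with target-species gene names through an ortholog
    map, and quantifies concordance between array beta values and bisulfite
    sequencing methylation ratios (Pearson correlation, error bins,
    Bland-Altman differences, inter-individual deltas). Includes a synthetic
    data generator with planted ground truth for end-to-end validation, and an
    exhaustive Smith-Waterman oracle for testing the aligner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
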