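Package: zeasweep
Title: Population-Genomic Selective-Sweep and Comparative-Genome Analysis for Maize Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic statistics (nucleotide diversity,
    Tajima's D, Weir-Cockerham FST), a cross-population composite likelihood
    ratio (XP-CLR) selective-sweep scan with LD-based SNP down-weighting,
    haplotype-group analysis at a single locus (SNP distance matrices, k-means
    haplotype clustering, per-group diversity, JC69 neighbor-joining trees),
    sweep-region calling from empirical score distributions, and pairwise
    genome-comparison procedures (genome-specific sequence and gene detection,
    conservation categories, pan-gene classification, k-mer genome-size
    estimation). Includes forward Wright-Fisher simulators that generate all
    required inputs with planted ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    rtracklayer,
    GenomicRanges,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
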