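Package: haploblock
Title: Structural Comparison of Tandemly Duplicated MHC Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assembling and comparing large-insert clone sets and
    haplotype sequences from tandemly duplicated gene regions such as the
    cattle MHC class I locus. Detects maximal end-overlaps between clones and
    tallies SNPs, indels and inversions within them; classifies coding effects
    of overlap SNPs; orders contigs against reference clones with gap
    estimation; validates assemblies by in-silico restriction digestion and
    tolerance-based fragment-profile matching; builds sliding-window identity
    matrices and detects tandem duplication blocks and their period; scans GC
    content for anomalously GC-rich tracts near exon boundaries; and performs
    segment-partitioned phylogenetics (Tamura three-parameter distances,
    neighbor-joining trees, Robinson-Foulds incongruence) to flag candidate
    gene-conversion breakpoints. Includes a synthetic-haplotype simulator with
    machine-readable truth records for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phangorn,
    rtracklayer,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
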