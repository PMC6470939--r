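Package: xylemiR
Title: Xylem-Sap Small RNA Analysis Under Cadmium Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for profiling mobile microRNAs in plant
    xylem sap from small RNA sequencing libraries. Covers adapter trimming and
    read collapsing, contaminant and low-complexity filtering, variant-aware
    matching of unique tags to reference mature miRNAs (isomiR naming), genome
    mapping, single stem-loop folding with MFEI-based precursor evaluation,
    classification of tags into known, arm-derived, homologous and novel miRNA
    candidates, cadmium-responsive differential expression by exact 2x2 tests on
    single-library counts, dual-scheme miRNA target prediction with consensus
    intersection, and degradome (PARE) cleavage-evidence scoring. Ships a fully
    seeded synthetic-data generator (genome with planted hairpins, three read
    libraries, transcriptome with planted target sites, degradome tag tables)
    so the whole pipeline is exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
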