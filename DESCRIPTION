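Package: hybridscan
Title: Windowed Divergence Ancestry Scans for Admixed and Hybrid Yeast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects the ancestry of admixed and hybrid Saccharomyces genomes
    from whole-genome alignments or variant calls. Implements the windowed
    minimum-divergence log2-ratio scan with permutation-based significance
    thresholds, breakpoint and region calling, a PCA-based 20-SNP-window local
    ancestry classifier, standard population-genetic statistics (nucleotide
    diversity, Tajima's D, Fu & Li's D/D*, Fu's Fs, Fay & Wu's H, Hudson's Fst,
    Tamura-Nei distances, ABBA-BABA D- and f4-statistics), coverage-based
    chromosome copy-number profiling, and a seed-deterministic population
    simulator with complete truth files for validating every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
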