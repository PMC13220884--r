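Package: phagetrace
Title: Genotype-Resolved Tracking of Phage Populations in Longitudinal Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bacteriophage genotypes and their dynamics from
    longitudinal metagenomic allele-frequency data. Starting from per-sample
    allele-depth tables, the package filters variants by read support and
    genome breadth, identifies near-clonal samples, derives haplotypes by
    deduplication and pigeonhole linking, clusters SNPs into linkage groups by
    trajectory similarity, decomposes mixed samples into genotype abundances
    on the probability simplex, and detects recombination (linkage decoupling)
    and novel mutation blocks. A ground-truthed serial-transfer metacommunity
    simulator emulates paired closed/open mesocosm experiments with phage
    migration, so every inference stage can be validated against known truth.
    Companion utilities cover viral detection and abundance metrics, direct
    terminal repeat and circular-permutation checks, ICTV-style rank
    demarcation from intergenomic similarity, and compositional community
    profiling (centered log-ratio transform, community typing, Bray-Curtis
    resilience comparisons).
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
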