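Package: viromeprofiler
Title: Gut Virome Profiling from Metagenomic Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for profiling phage communities in
    human gut metagenomes. Classifies assembled contigs as phage or bacterial
    from upstream virus-prediction evidence, detects circular contigs,
    deduplicates at nucleotide identity, groups phage contigs into viral
    clusters (VCs) by shared protein-cluster content (hypergeometric
    similarity network plus Markov clustering), builds coverage-filtered RPKM
    abundance tables, predicts phage-host links from CRISPR protospacers,
    prophage taxonomy and reference co-clustering, delineates marker-gene
    phage lineages with subfamily structure, and runs the two-group ecology
    and prevalence statistics used in case/control virome studies. A
    deterministic synthetic-community generator with planted ground truth
    makes every stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
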