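Package: petalbull
Title: Transcriptome Phylogenomics and Quantitative Genetics of Petal
    Bullseye Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain used to
    study the evolution of petal bullseye pigmentation in a small Hibiscus
    clade: redundancy reduction and Markov clustering of transcript
    similarity graphs into homolog groups, tree-based homology cleaning
    (long-tip trimming, monophyly masking, deep-paralog cutting),
    Maximum-Inclusion ortholog extraction, and an exact maximum-quartet-support
    species tree with branch lengths in coalescent units. Downstream
    statistics cover differential-expression filtering with
    Benjamini-Hochberg adjustment, efficiency-corrected (Pfaffl-type) qPCR
    relative expression, Mendelian F2 segregation and genotype-phenotype
    co-segregation tests, spectrophotometric flavonoid quantification, and
    pollinator-preference tests. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
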