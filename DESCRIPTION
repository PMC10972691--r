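Package: invdemog
Title: Dating Chromosomal Inversions with Blockwise Site Frequency Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic inference for pairs of diverging species whose genomes
    differ by alternatively fixed chromosomal inversions. Summarizes diploid
    genotype data as the blockwise site frequency spectrum (bSFS), computes
    exact mutation-configuration probabilities under strict-divergence (DIV)
    and unidirectional isolation-with-migration (IM) coalescent models via a
    structured-coalescent Markov chain, and fits these models by composite
    likelihood to date inversions relative to the species split. Includes a
    synthetic-data generator (genotypes, masks, caller-style structural-variant
    tables), variant preprocessing and genome partitioning, d_xy / pi / F_ST
    and sliding-window scans, parametric-bootstrap model comparison, a
    gene-conversion-only simulation null for inversion divergence, and a
    consensus filter for fixed inversions reported by two SV callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
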