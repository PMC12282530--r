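Package: hierepi
Title: Hierarchical Epistasis Models for Overdispersed Branching Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of inflorescence branching
    in multi-locus segregating plant populations. Provides negative-binomial
    and Poisson count likelihoods with per-plant exposure, additive/dominance
    and pairwise-interaction design matrices over biallelic and multi-allelic
    loci, a hierarchical multilinear epistasis model in which mutations in one
    paralogue pair rescale the effects of mutations in the other, genotype-season
    maximum-likelihood phenotype estimation with shared overdispersion,
    total-least-squares background-rescaling analysis, model comparison and
    synergy contrasts, cross-validation, and a Mendelian F2-cross simulator
    for closed-loop parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
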