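Package: meioCO
Title: Cytological Analysis of Meiotic Crossover Interference and
    Recombination Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of immunofluorescent recombination foci
    on spread meiotic chromosomes. Provides synaptonemal complex (SC)
    length metrics with size-rank grouping, gamma-renewal modelling of
    crossover interference with maximum-likelihood shape estimation
    corrected for the finite observable distance window, positional
    analysis of MLH1 crossover foci along the centromere-telomere axis,
    and the contingency and rank statistics used in focus-count
    comparisons (Fisher's exact, G test, Mann-Whitney, Anderson-Darling
    k-sample). A seeded meiocyte simulator generates synthetic datasets
    with the same statistical structure, so every stage of the pipeline
    can be verified without microscopy data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
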