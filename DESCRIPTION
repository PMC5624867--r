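Package: biodistr
Title: Biodistance Analysis with R-Matrix Kinship Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative biodistance analysis of population samples from
    neutral genetic markers and dental phenotypes. Estimates population
    kinship (R) matrices from allele frequencies (SNP or STR), from
    individual-level metric traits under the Relethford-Blangero
    quantitative-genetic model, and from binary non-metric traits under the
    liability threshold model; estimates long-term effective population size
    from linkage-disequilibrium decay for weighting; and compares the
    resulting kinship structures with permutation-based Mantel and
    Dow-Cheverud tests and principal coordinates analysis. Includes a
    synthetic-data generator with a known ground-truth kinship matrix so
    every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
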