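Package: mirvar
Title: Allele-Aware MicroRNA Seed-Site Scanning and Candidate-Variant
    Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational chain of a candidate-gene study of a
    regulatory 3'UTR variant: an exhaustive, allele-aware scan for microRNA
    seed sites (6mer/7mer-A1/7mer-m8/8mer) created or destroyed by a
    single-nucleotide substitution, carrier-model case-control association
    (Pearson chi-square, odds ratio with Woolf confidence interval, minor
    allele frequencies, Fisher's exact test), genotype-stratified phenotype
    comparisons (t tests, one-way ANOVA with Sidak multiple comparisons),
    qPCR relative quantification (spike-in and housekeeping delta-Ct,
    dual-reporter fold changes), and seeded synthetic-data generators so the
    whole pipeline runs and is testable without any external download.
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
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
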