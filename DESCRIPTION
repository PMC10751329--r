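Package: hybridase
Title: Allele-Specific Expression and Cis/Trans Regulatory Analysis in F1
    Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of nonadditive and allele-specific expression (ASE) of a
    candidate gene in an F1 interspecific hybrid. Discovers diagnostic SNPs by
    pairwise comparison of parental coding sequences, quantifies relative
    expression from qPCR Ct tables by the 2^-ddCt method, tests hybrid
    expression against the midparent value, estimates maternal allelic
    fractions from pyrosequencing-style allele counts, and decomposes
    regulatory divergence into cis and trans components (A = log2 parental
    ratio, B = log2 hybrid allelic ratio, trans = A - B) with an
    enhancing/compensating classification. Includes a synthetic-data generator
    that plants known cis and trans effects so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
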