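Package: degcrosstalk
Title: Crosstalk Analysis of Combined-Stress Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the transcriptional interaction between two
    stresses applied alone and in combination, from per-contrast differential
    expression tables. Provides signed DEG calling at configurable fold-change
    and adjusted-p cutoffs, two- and three-set Venn partitioning (from gene
    lists or from published summary counts), directionality and amplitude
    concordance between datasets, transcriptome-proteome fold-change
    concordance, similarity / suppression / novel-interaction crosstalk scores,
    chi-squared overlap testing against a gene universe, hypergeometric term
    enrichment with Benjamini-Hochberg correction, and a synthetic experiment
    generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
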