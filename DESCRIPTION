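Package: fermeta
Title: Amplicon and Shotgun Metagenomics of Rice-Wine Fermentation Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for profiling the microbial communities of cereal-based
    wine fermentations and predicting final wine quality from early
    community state. Implements amplicon tag quality control, greedy
    OTU clustering with chimera screening, rarefaction, genus-level
    profiling, diversity and ordination statistics with permutation
    tests, a day-7 decision-tree spoilage predictor driven by
    Lactobacillus dominance, shotgun-read quality control with cereal
    decontamination, paired valid-hit species abundance with
    gap-adjusted genome lengths, contig post-processing with N50-based
    assembly selection and a three-step bacteria/fungi domain
    classifier, non-redundant gene-catalogue construction, and
    quorum-sensing, antibiotic-resistance and KEGG marker-gene
    functional profiling. A synthetic-data module generates every
    input with known ground truth for end-to-end validation.
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
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
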