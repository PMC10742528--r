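Package: hippotrio
Title: Panel-Agnostic Trio Variant Prioritisation and Gene-Panel Tiering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritises rare-disease variants in sequenced trios with a
    panel-agnostic filter cascade for variants of high pathogenic potential
    (inheritance model, population and cohort allele frequency, CADD and
    SpliceAI scores, ClinVar status, call quality), restricts candidates to
    GenCC disease genes, and emulates the UK Genomic Medicine Service
    panel-based tiering strategy (Tier 1/Tier 2 against PanelApp green genes
    plus gene-agnostic de novo and Exomiser branches). Includes a synthetic
    trio-cohort generator with planted causal variants, readers and writers
    for the annotated VCF/PED/TSV artifacts involved, and the comparison
    statistics (diagnostic and reportable rates per variant assessed, paired
    Wilcoxon signed-rank, Fisher's exact test) used to contrast the two
    strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
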