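Package: clonalshift
Title: Germline-Somatic Interaction Analysis for Myeloid Clonal Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for studying the interplay between inherited risk
    haplotypes and acquired clonal events in myeloid disease. Detects
    mosaic chromosomal alterations (gain, loss, copy-neutral LOH) from
    phased SNP-array B-allele frequency and log2 R ratio signal, estimates
    cellular fractions by allele-copy accounting, calls JAK2 V617F
    mutations and their cis/trans phase relative to the 46/1 germline risk
    haplotype from targeted long-read haplotype tables, and computes
    allelic-shift binomial tests, co-occurrence and clonal-ordering
    statistics. Includes a telomere-length polygenic score, a Mendelian
    randomization estimator suite (IVW, Egger, median, maximum likelihood)
    with pleiotropy pruning, liability-scale heritability conversion, and
    qPCR relative telomere length computation. A synthetic-cohort
    generator reproduces the statistical structure of a myelofibrosis
    case series so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
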