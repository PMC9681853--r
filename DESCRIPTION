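Package: pancanscreen
Title: Pan-Cancer Screening for Consistently Dysregulated Focal Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening a focal gene (or gene family)
    for consistent dysregulation across cancer cohorts: per-cancer
    tumor-versus-healthy differential expression with a family-wide binomial
    consistency test, genome-wide empirical-null (one-sample Z) tests for
    aneuploidy association and mutation-rate depletion, preranked gene-set
    enrichment (running-sum enrichment score, permutation NES, BH FDR),
    differential co-expression via Delta NES against transcription-factor
    target sets, tumor stratification by upstream-regulator expression,
    oncogene-overexpression effect testing, promoter methylation testing, and
    background-subtracted immunofluorescence intensity ratios. Includes a
    synthetic multi-cancer cohort generator that plants every effect the
    analysis assumes, so each stage has a parameter-recovery oracle.
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
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
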