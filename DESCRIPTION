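Package: trioconcord
Title: Parentage Quality Control for SNP-Array Trio Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confirms maternity and paternity in trio chromosomal-microarray
    studies from the SNP genotype tables the arrays export. Each
    proband-parent pairing is reduced to the loci at which both samples are
    two-copy homozygotes; opposite-homozygote (Mendelian-impossible) loci are
    counted and a true-pair is called when their proportion falls below a
    clinical threshold, with a trio confirmed only when both parents pass.
    Includes a Hardy-Weinberg pedigree simulator (founders, Mendelian
    transmission, siblings, genotyping error, no-calls, copy-number-abnormal
    calls) so the separation of true from false pairs is reproducible without
    patient data, plus cohort cross-matching, tidy and glance summaries,
    ggplot2 plotting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
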