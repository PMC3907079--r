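Package: descna
Title: Dosage Effect Scoring for Paired Copy-Number and Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how somatic copy-number alterations translate into
    concordant expression changes across a tumor cohort via a per-gene
    dosage effect score (DES): the fraction of copy-altered samples whose
    expression shifts beyond one standard deviation of the copy-neutral
    mean, in the direction of the alteration.  Includes SNP-to-gene
    copy-number summarization, hyperdiploid/non-hyperdiploid subtype
    calling from trisomy-chromosome copy numbers, moderated differential
    expression with false discovery rate control, Fisher-exact gene-set
    enrichment, Cochran-Armitage trend testing, a genome-wide karyotype
    plot of gain/loss frequencies colored by DES, and a synthetic
    paired-cohort simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
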