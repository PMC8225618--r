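Package: ARVquant
Title: Androgen Receptor Splice-Variant Quantification from Junction Reads
    and Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies androgen receptor (AR) splice variants (AR-FL,
    AR-V7, AR-v567es) from two complementary data types: spliced RNA-Seq
    alignments, by counting reads whose splice exactly bridges each
    variant's discriminating exon-exon junction, and droplet digital PCR
    (ddPCR) amplitude exports, by Poisson-based absolute quantification
    with plate-control QC and repeatability statistics. Includes cohort
    analytics (prevalence summaries, two-tailed Fisher exact enrichment
    by full hypergeometric enumeration, Mann-Whitney group comparisons on
    log2 counts) and synthetic-data generators for droplets, spliced SAM
    reads, and patient cohorts, so the full pipeline runs without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicAlignments,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
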