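Package: polpause
Title: Promoter-Proximal RNA Polymerase II Pausing Analysis from
    Nascent-Transcription Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of promoter-proximal RNA polymerase II
    pausing from strand-specific single-nucleotide nascent-transcription
    coverage (NET-seq, PRO-seq). Computes a per-gene pausing index
    (promoter window density over gene-body density), applies
    gene-selection and signal-eligibility filters, classifies differential
    pausing between two conditions with a replicate-consistency rule,
    stratifies genes by pausing quantile and by promoter RNA cross-link
    presence (PAR-CLIP), normalizes signal by nascent expression, selects
    expression-matched control gene sets, and builds reference-point and
    scaled-gene-body metagene profiles. Includes a seeded synthetic-data
    generator that plants known pausing structure for end-to-end
    validation, and a pipeline driver with a reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
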