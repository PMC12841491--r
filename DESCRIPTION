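Package: cnvmask
Title: Recurrence-Based Problematic-Region Masking for Exome CNV Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Benchmarks exome-sequencing copy-number-variant (CNV) callers
    against an orthogonal array-derived truth set at the capture-bait level,
    and improves caller precision by detecting caller-specific "problematic
    regions": baits where a caller emits CNV calls in more than a threshold
    fraction of a cohort. Provides the truth-set filter cascade (SNP-probe
    count, polymorphic-locus and bait-overlap filters), exon-level
    sensitivity/PPV benchmarking with cross-caller concordance, cohort
    recurrence masking, bait annotation (mappability, GC content, RPKM
    coefficient of variation, segmental-duplication overlap) with a
    resampling Wilcoxon comparison of flagged versus background baits,
    mask-based filtration with paired signed-rank pre/post tests, and a
    seeded synthetic-cohort generator so the whole pipeline is testable
    without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
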