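Package: beefcand
Title: Candidate-Gene Screening for Beef Quality from Bovine Muscle RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prioritising beef-quality candidate genes from
    bull-versus-steer longissimus lumborum RNA-seq. Implements Phred-based
    read-level quality filters with Q20/Q30/GC summaries, FPKM quantification
    with expression-level binning, a plumbing differential-expression test with
    Benjamini-Hochberg FDR calling, two-sample trait comparisons reproducible
    from printed mean/SE summaries, positional screening of differentially
    expressed genes against QTL regions and GWAS SNPs with intersection to a
    candidate set, and 2^-ddCt qPCR validation against dual reference genes.
    A seeded synthetic-data module generates every pipeline input with planted
    ground truth so all stages are testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    nortest,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
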