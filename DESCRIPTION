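Package: srdetect
Title: Differential Alternative Splicing Detection from Splice-Junction
    Splicing Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects differential alternative splicing events between
    treatment and control RNA-seq samples from splice-junction read
    counts. Junctions sharing a 5' or 3' splice site are converted to
    splicing ratios (SR); each event in each treatment sample is scored
    with the splicing-ratio-difference statistic (srd), whose per-sample
    distribution is fitted with a heavy-tailed (power-law) null so that
    tail probabilities give event significance; candidates are selected
    by the median significance across treatment samples against a
    dynamic background threshold derived from leave-one-out control
    comparisons, and ranked by isoform-expression differences. Includes
    cassette-exon, alternative 3'/5' splice-site and mutually-exclusive-
    exon classification from junction geometry and exon annotation, a
    cohort-association stage (event frequency filter, Fisher's exact
    association with a binary group, log-rank and Cox hazard-ratio
    survival association, Venn-style set intersections), a protein-
    microarray spot filter (SNR, fold change, duplicate-spot CV), and a
    synthetic-data generator producing junction counts, isoform tables,
    cohorts and spot tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
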