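Package: trtscreen
Title: Patient-Specific Transcriptional Read-Through Screening for RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects patient-specific transcriptional read-through (TRT) in
    bulk RNA-seq cohorts by a four-step screen over adjacent gene pairs:
    candidate pair enumeration from a gene annotation, fragment coverage
    and FPKM quantification of gene bodies and intergenic intervals,
    fold-change thresholding against a healthy-control baseline, and
    recurrence selection across patients. Companion analyses cover TRT
    burden statistics against clinical traits (Wilcoxon rank-sum, Spearman
    correlation, chi-square), a PCA-based gene-set activity score for the
    NETosis pathway with orientation diagnostics, and cis/trans target
    prediction for long non-coding RNAs by genomic proximity and
    co-expression. A seeded synthetic-cohort generator with planted
    read-through events and trait couplings provides ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
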