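Package: reprodyn
Title: Transcriptional and Epigenetic Dynamics of Reprogramming Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of multi-omic time courses from somatic-cell
    reprogramming experiments, built around the transition from human fibroblasts
    to naive induced pluripotent stem cells. Provides stage-specificity scoring of
    genes and transposable elements against an embryo-stage reference,
    correlation-distance k-means clustering of differentially expressed genes,
    repeat-family and repeat-class FPKM quantification from genomic coverage,
    per-cytosine differential methylation calling with region merging and
    naive-specific region logic, rule-based four-state promoter chromatin-state
    classification with transition accounting and TSS signal profiles,
    CpG-density promoter classification, and per-gene integration of expression,
    methylation and histone dynamics. A synthetic-data module generates every
    input with planted ground truth so the full pipeline is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
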