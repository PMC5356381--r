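Package: methcore
Title: Integrated Promoter Methylation and Expression Analysis for
    Matched Tumor/Normal Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrated analysis of reduced representation
    bisulfite sequencing (RRBS) promoter methylomes and RNA-seq
    transcriptomes in matched tumor/normal designs. Classifies promoters
    by CpG density (HCP/ICP/LCP) with a sliding-window CpG ratio and GC
    content rule, calls differentially methylated promoters by a
    per-feature-class top-quantile rule on tumor-normal methylation
    differences, applies per-pair fold-change differential-expression
    rules, runs a novel-lincRNA filter cascade over assembled transcript
    models and coding-potential scores, intersects differential
    methylation with differential expression under a sign-consistency
    rule gated on CpG-island promoters, and builds a core co-function
    network from permutation-tested co-expression, Wang-measure GO
    semantic similarity, and co-methylation. Includes a synthetic-data
    generator that emits all pipeline inputs with planted, recoverable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
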