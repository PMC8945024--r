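Package: epistim
Title: Differential Methylation and Expression Analysis for Stimulated Monocyte Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of paired DNA methylation (EPIC-style beta
    values) and RNA-seq responses in short in vitro stimulation time courses
    with a small number of donors. Provides probe-level quality filtering,
    per-probe moderated linear models with donor blocking on the M-value
    scale, delta-beta DMP calling, gap-chained DMR calling, RPKM-based
    differential expression with a sign-agreement noise filter, a multi-arm
    category engine (differentiation-associated, attenuated,
    treatment-specific and unique co-stimulation signatures, tertile
    response classes), nearest-gene and promoter/distal annotation, PWM
    motif and term enrichment with composite filters, and summary reporting
    (z-scored matrices, PCA, median trajectories). A synthetic-data module
    generates methylation, expression and sequence inputs with planted
    effect classes and a ground-truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
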