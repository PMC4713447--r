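Package: beeMZT
Title: Maternal-to-Zygotic Transition Analysis for Honeybee Embryogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stage-wise analysis of the maternal-to-zygotic transition (MZT)
    in honeybee (Apis mellifera) embryogenesis from RNA-seq count data.
    Implements RPKM quantification with a mapped-read cutoff, the MARS
    (MA-plot with random sampling model) differential-expression statistic,
    classification of transcripts into maternal (class I), zygotic (class II)
    and maternal-degraded-then-resynthesized (class III) expression profiles
    across mature oocytes and haploid/diploid embryo stages, exact mapping of
    19-24 nt small-RNA reads to miRNA hairpins with 5p/3p arm assignment,
    TAGteam promoter-motif discovery by exhaustive k-mer coverage scoring with
    PWM comparison, and miRNA-target network inference combining stage-profile
    anticorrelation with nearest-neighbor duplex free-energy scoring. A seeded
    synthetic-study generator with planted ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
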