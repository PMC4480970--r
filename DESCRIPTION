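Package: TregDissect
Title: Bimodal Expression Classification and Regulation Calling for
    Transcription-Factor Domain Dissection
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the transcriptional consequences of
    transcription-factor domain mutations from bulk RNA-seq count data,
    built around the regulatory-T-cell Foxp3 study design. Provides robust
    FPKM normalisation, expectation-maximization fitting of the bimodal
    log2-FPKM expression distribution with FDR-based low/high expression
    class boundaries, a negative-binomial Wald differential-expression
    stage with moderated log2 fold changes, direction-aware calling of
    retained versus dysregulated genes per mutant, exact binomial and
    Fisher statistics on gene-set direction splits, sample distances and
    PCA, a proline-framed conservation/selection scan over protein
    alignments, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
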