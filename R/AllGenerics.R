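#' @importFrom BiocGenerics counts estimateDispersions sizeFactors
#'   sizeFactors<-
NULL

#' @export
setGeneric("geneLengths", function(object) standardGeneric("geneLengths"))

#' @export
setGeneric("sampleConditions",
           function(object) standardGeneric("sampleConditions"))

#' @export
setGeneric("expressionClasses",
           function(object) standardGeneric("expressionClasses"))

#' Accessors for FoxExperiment
#'
#' \code{counts} returns the integer count matrix; \code{geneLengths} the
#' per-gene transcript lengths (bases); \code{sampleConditions} the
#' per-sample condition labels; \code{sizeFactors} the median-of-ratios size
#' factors (NULL before [computeSizeFactors()] has been applied);
#' \code{expressionClasses} the per-(gene, sample) NE/LE/INT/HE labels
#' (NULL before [classifyGenes()]).
#'
#' @param object a \linkS4class{FoxExperiment}.
#' @return see above.
#' @name FoxExperiment-accessors
NULL

#' @rdname FoxExperiment-accessors
#' @export
setMethod("counts", "FoxExperiment", function(object) {
    assay(object, "counts")
})

#' @rdname FoxExperiment-accessors
#' @export
setMethod("geneLengths", "FoxExperiment", function(object) {
    stats::setNames(rowData(object)$gene_length, rownames(object))
})

#' @rdname FoxExperiment-accessors
#' @export
setMethod("sampleConditions", "FoxExperiment", function(object) {
    stats::setNames(colData(object)$condition, colnames(object))
})

#' @rdname FoxExperiment-accessors
#' @export
setMethod("sizeFactors", "FoxExperiment", function(object) {
    if ("sizeFactor" %in% colnames(colData(object)))
        stats::setNames(colData(object)$sizeFactor, colnames(object))
    else NULL
})

#' @rdname FoxExperiment-accessors
#' @param value numeric vector of positive per-sample size factors.
#' @export
setReplaceMethod("sizeFactors", "FoxExperiment", function(object, value) {
    stopifnot(length(value) == ncol(object), all(value > 0))
    colData(object)$sizeFactor <- as.numeric(value)
    object
})

#' @rdname FoxExperiment-accessors
#' @export
setMethod("expressionClasses", "FoxExperiment", function(object) {
    if ("class" %in% assayNames(object)) assay(object, "class") else NULL
})
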