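#' Median-of-ratios size factors
#'
#' Computes per-sample normalisation factors by the median-of-ratios
#' convention: the reference for each gene is the geometric mean of its
#' counts across samples, restricted to genes with no zero count anywhere;
#' a sample's factor is the median over those genes of count/reference.
#'
#' @param object a \linkS4class{FoxExperiment} or a count matrix.
#' @return for a matrix, a named numeric vector of positive factors; for a
#'   \code{FoxExperiment}, the object with factors stored (retrieve with
#'   \code{sizeFactors()}).
#' @examples
#' k <- matrix(c(1:5, 2 * (1:5)), ncol = 2)
#' computeSizeFactors(k)   # c(1/sqrt(2), sqrt(2))
#' @export
computeSizeFactors <- function(object) {
    if (is(object, "FoxExperiment")) {
        sizeFactors(object) <- computeSizeFactors(counts(object))
        return(object)
    }
    k <- as.matrix(object)
    keep <- rowSums(k == 0) == 0
    if (!any(keep))
        stop("cannot form reference: every gene has a zero count in some sample")
    logk <- log(k[keep, , drop = FALSE])
    ref <- rowMeans(logk)                     # log geometric mean
    sf <- apply(logk, 2, function(col) exp(stats::median(col - ref)))
    stats::setNames(sf, colnames(k))
}

#' Robust FPKM
#'
#' Fragments per kilobase of transcript per million mapped fragments, with
#' the library scale normalised by median-of-ratios size factors:
#' \deqn{FPKM_{gj} = \frac{k_{gj}/s_j}{(L_g/10^3)\,(S_j/10^6)}}
#' where \eqn{s_j} is the size factor and \eqn{S_j} the column total of the
#' normalised counts. Zero counts map to zero FPKM.
#'
#' @param object a \linkS4class{FoxExperiment}.
#' @param sf optional size factors; computed from the counts when missing.
#' @return the object with an \code{"fpkm"} assay (and a \code{"log2fpkm"}
#'   assay, \code{-Inf} at zero counts) added.
#' @export
computeFPKM <- function(object, sf = NULL) {
    stopifnot(is(object, "FoxExperiment"))
    if (is.null(sf)) {
        if (is.null(sizeFactors(object)))
            object <- computeSizeFactors(object)
        sf <- sizeFactors(object)
    } else {
        sizeFactors(object) <- sf
    }
    len <- geneLengths(object)
    if (any(is.na(len)) || any(len <= 0))
        stop("all genes need a positive length")
    norm <- sweep(counts(object), 2, sf, "/")
    S <- colSums(norm)
    fpkm <- sweep(norm, 1, len / 1e3, "/")
    fpkm <- sweep(fpkm, 2, S / 1e6, "/")
    assay(object, "fpkm") <- fpkm
    assay(object, "log2fpkm") <- log2(fpkm)
    object
}

#' Shifted-log expression for distances, clustering and PCA
#'
#' A simple regularising transform, \code{log2(normalised count + 1)}, used
#' where a variance-stabilised expression measure is needed for sample
#' distances, hierarchical clustering and PCA. It is a deliberate stand-in
#' for heavier regularised-log transforms; those outputs are qualitative.
#'
#' @param object a \linkS4class{FoxExperiment}.
#' @param genes optional gene identifiers to restrict to (e.g. the regulated
#'   set).
#' @return numeric matrix, genes x samples.
#' @export
regLog <- function(object, genes = NULL) {
    stopifnot(is(object, "FoxExperiment"))
    if (is.null(sizeFactors(object)))
        object <- computeSizeFactors(object)
    norm <- sweep(counts(object), 2, sizeFactors(object), "/")
    if (!is.null(genes)) norm <- norm[genes, , drop = FALSE]
    log2(norm + 1)
}
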