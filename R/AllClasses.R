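#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData rowData<- colData colData<-
NULL

#' FoxExperiment: an RNA-seq count container with gene lengths and sample
#' condition labels
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding an integer
#' \code{"counts"} assay, per-gene transcript lengths (sum of non-overlapping
#' exonic bases) in \code{rowData()$gene_length}, and per-sample
#' \code{condition} and \code{replicate} labels in \code{colData()}. All
#' downstream stages (FPKM, expression classes, differential expression,
#' regulation calling) operate on this object.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#' @seealso [FoxExperiment()] for the constructor.
#' @export
setClass("FoxExperiment", contains = "SummarizedExperiment")

setValidity("FoxExperiment", function(object) {
    msg <- character(0)
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (any(!is.finite(k)) || any(k < 0))
            msg <- c(msg, "counts must be finite and non-negative")
        else if (any(abs(k - round(k)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    if (!"gene_length" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'gene_length'")
    else if (any(!is.finite(rowData(object)$gene_length)) ||
             any(rowData(object)$gene_length <= 0))
        msg <- c(msg, "gene lengths must be positive")
    for (col in c("condition", "replicate"))
        if (!col %in% colnames(colData(object)))
            msg <- c(msg, sprintf("colData must contain '%s'", col))
    if (length(msg)) msg else TRUE
})

#' Construct a FoxExperiment
#'
#' @param counts integer matrix of read counts, genes in rows, samples in
#'   columns. Row and column names are used as gene and sample identifiers.
#' @param geneLengths positive numeric vector of transcript lengths in bases,
#'   one per gene (recycled names checked against \code{rownames(counts)} when
#'   named).
#' @param condition character vector of condition labels, one per sample.
#' @param replicate optional replicate labels per sample; defaults to the
#'   within-condition running index.
#' @return A \linkS4class{FoxExperiment}.
#' @examples
#' k <- matrix(rpois(20, 50), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' fe <- FoxExperiment(k, geneLengths = rep(1000, 5),
#'                     condition = rep(c("control", "foxp3"), each = 2))
#' @export
FoxExperiment <- function(counts, geneLengths, condition, replicate = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample%02d", seq_len(ncol(counts)))
    if (length(geneLengths) != nrow(counts))
        stop("geneLengths must have one entry per gene")
    if (!is.null(names(geneLengths)) &&
        !identical(names(geneLengths), rownames(counts)))
        geneLengths <- geneLengths[rownames(counts)]
    if (length(condition) != ncol(counts))
        stop("condition must have one entry per sample")
    condition <- as.character(condition)
    if (is.null(replicate)) {
        replicate <- stats::ave(seq_along(condition), condition,
                                FUN = seq_along)
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(gene_length = as.numeric(geneLengths),
                            row.names = rownames(counts)),
        colData = DataFrame(condition = condition,
                            replicate = as.character(replicate),
                            row.names = colnames(counts)))
    new("FoxExperiment", se)
}

#' Two-component Gaussian mixture fit of a log2-FPKM distribution
#'
#' Parameters of the unequal-variance two-component Gaussian mixture fitted
#' by EM to the log2 FPKM values of expressed genes in one sequencing
#' replicate. Components are always ordered so the low-expression (LE)
#' component has the smaller mean.
#'
#' @slot piLE,piHE component weights, summing to one.
#' @slot muLE,muHE component means on the log2-FPKM scale.
#' @slot sigmaLE,sigmaHE component standard deviations (> 0).
#' @slot logLik fitted log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood of the best run
#'   (non-decreasing).
#' @slot nPoints number of values fitted.
#' @slot converged whether EM converged within the iteration budget.
#' @export
setClass("MixtureFit",
    representation(piLE = "numeric", piHE = "numeric",
                   muLE = "numeric", muHE = "numeric",
                   sigmaLE = "numeric", sigmaHE = "numeric",
                   logLik = "numeric", logLikTrace = "numeric",
                   nPoints = "integer", converged = "logical"))

setValidity("MixtureFit", function(object) {
    msg <- character(0)
    if (object@muLE >= object@muHE)
        msg <- c(msg, "components must be ordered: muLE < muHE")
    if (object@sigmaLE <= 0 || object@sigmaHE <= 0)
        msg <- c(msg, "sigmas must be positive")
    if (object@piLE <= 0 || object@piLE >= 1 ||
        abs(object@piLE + object@piHE - 1) > 1e-8)
        msg <- c(msg, "weights must lie in (0,1) and sum to 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn MixtureFit-class compact display.
#' @param object a \code{MixtureFit}.
#' @export
setMethod("show", "MixtureFit", function(object) {
    cat("MixtureFit (2-component Gaussian, log2 FPKM)\n")
    cat(sprintf("  LE: pi = %.3f, mu = %.3f, sigma = %.3f\n",
                object@piLE, object@muLE, object@sigmaLE))
    cat(sprintf("  HE: pi = %.3f, mu = %.3f, sigma = %.3f\n",
                object@piHE, object@muHE, object@sigmaHE))
    cat(sprintf("  logLik %.2f on %d points; converged: %s\n",
                object@logLik, object@nPoints, object@converged))
})

#' LE/HE expression-class boundaries at a target false discovery rate
#'
#' Thresholds on log2 FPKM delimiting the lowly-expressed (LE) and
#' highly-expressed (HE) classes, derived from a \linkS4class{MixtureFit} so
#' that the contamination of each called class by the opposite component is
#' held at the requested FDR. Values strictly between the bounds are
#' intermediate (INT).
#'
#' @slot tLE upper log2-FPKM bound of the LE class.
#' @slot tHE lower log2-FPKM bound of the HE class (\code{tLE <= tHE}).
#' @slot fdr the FDR level used.
#' @slot method "tail" (tail-overlap FDR, default) or "posterior".
#' @slot degenerate TRUE when the components are so separated that the FDR
#'   constraint holds everywhere between the means; both bounds are then set
#'   to the crossing of the two scaled component densities.
#' @export
setClass("ClassBoundaries",
    representation(tLE = "numeric", tHE = "numeric", fdr = "numeric",
                   method = "character", degenerate = "logical"))

setValidity("ClassBoundaries", function(object) {
    if (object@tLE > object@tHE + 1e-9)
        "tLE must not exceed tHE" else TRUE
})

#' @describeIn ClassBoundaries-class compact display.
#' @param object a \code{ClassBoundaries}.
#' @export
setMethod("show", "ClassBoundaries", function(object) {
    cat(sprintf(
        "ClassBoundaries: tLE = %.4f, tHE = %.4f (fdr %.3g, %s%s)\n",
        object@tLE, object@tHE, object@fdr, object@method,
        if (object@degenerate) ", degenerate" else ""))
})

#' Differential-expression result table
#'
#' One row per gene with base mean of normalized counts, moderated log2 fold
#' change (numerator vs denominator condition), its standard error, Wald
#' statistic, two-sided p-value, BH-adjusted p-value and the dispersion used.
#' Untestable genes (all-zero counts) carry NA statistics and are excluded
#' from the multiple-testing correction. The contrast and shrinkage prior are
#' recorded in \code{metadata()}.
#'
#' @export
setClass("DEResult", contains = "DFrame")

#' Per-gene regulation table
#'
#' One row per gene: \code{regulated} (TRUE when the gene is regulated by the
#' factor and relevant to the reference lineage, i.e. differentially
#' expressed in both defining contrasts), \code{direction} ("up"/"down" by
#' the factor, NA when not regulated), and one \code{status_<mutant>} column
#' per scored mutant with values "retained", "dysregulated" or "untested".
#'
#' @export
setClass("RegulationTable", contains = "DFrame")

#' Configuration of the synthetic study generator
#'
#' Describes a synthetic transcription-factor domain-dissection study:
#' a bimodal log2-FPKM expression landscape, a planted set of
#' factor-regulated genes with up/down directions, and mutant conditions
#' that revert ("dysregulate") chosen subsets of those effects toward the
#' control mean. See [simulateCounts()].
#'
#' @slot nGenes number of genes.
#' @slot conditions condition names; must contain "naive_th", "treg",
#'   "control" and "foxp3"; any further names are mutants.
#' @slot nReplicates replicates per condition.
#' @slot piLE fraction of expressed genes in the low-expression mode.
#' @slot muLE,sigmaLE,muHE,sigmaHE Gaussian parameters of the two
#'   log2-FPKM modes.
#' @slot fracZero fraction of genes with zero counts everywhere (NE).
#' @slot nRegulated number of factor-regulated genes.
#' @slot fracUp fraction of regulated genes upregulated by the factor.
#' @slot effectRange interval of absolute log2 fold changes planted for
#'   regulated genes.
#' @slot mutantDysregulation named list, one entry per mutant condition:
#'   either a single fraction in [0,1] (that share of regulated genes is
#'   sampled) or an integer vector of indices into the regulated gene set
#'   (explicit planting, e.g. for disjoint or nested designs).
#' @slot dysregMultiplier reversion strength: 1 (default) reverts a
#'   dysregulated gene fully to the control mean; values in (0,1) give
#'   partial reversion.
#' @slot dispAlpha0,dispAlphaScale,dispAlphaMax negative-binomial dispersion
#'   trend alpha(mu) = min(alphaMax, alpha0 + alphaScale/mu) on the scale of
#'   mean counts.
#' @slot librarySizeRange interval of per-sample total-count scalers.
#' @slot geneLengthRange interval of transcript lengths in bases.
#' @slot seed integer seed driving a single pseudo-random stream.
#' @export
setClass("SimulationConfig",
    representation(nGenes = "integer", conditions = "character",
                   nReplicates = "integer",
                   piLE = "numeric", muLE = "numeric", sigmaLE = "numeric",
                   muHE = "numeric", sigmaHE = "numeric",
                   fracZero = "numeric", nRegulated = "integer",
                   fracUp = "numeric", effectRange = "numeric",
                   mutantDysregulation = "list",
                   dysregMultiplier = "numeric",
                   dispAlpha0 = "numeric", dispAlphaScale = "numeric",
                   dispAlphaMax = "numeric",
                   librarySizeRange = "numeric",
                   geneLengthRange = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character(0)
    fr <- c(piLE = object@piLE, fracZero = object@fracZero,
            fracUp = object@fracUp)
    if (any(fr < 0 | fr > 1))
        msg <- c(msg, "piLE, fracZero and fracUp must lie in [0,1]")
    if (object@nRegulated > object@nGenes * (1 - object@fracZero))
        msg <- c(msg, "nRegulated exceeds the number of expressed genes")
    if (length(object@effectRange) != 2 || any(object@effectRange <= 0) ||
        diff(object@effectRange) < 0)
        msg <- c(msg, "effectRange must be a strictly positive interval")
    core <- c("naive_th", "treg", "control", "foxp3")
    if (!all(core %in% object@conditions))
        msg <- c(msg, paste("conditions must include",
                            paste(core, collapse = ", ")))
    mut <- setdiff(object@conditions, core)
    bad <- setdiff(names(object@mutantDysregulation), mut)
    if (length(bad))
        msg <- c(msg, paste("mutantDysregulation names absent from",
                            "conditions:", paste(bad, collapse = ", ")))
    for (v in object@mutantDysregulation) {
        if (is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1) next
        if (is.numeric(v) && all(v == round(v)) && all(v >= 1) &&
            all(v <= object@nRegulated)) next
        msg <- c(msg, "each mutantDysregulation entry must be a fraction in [0,1] or indices into the regulated set")
    }
    if (object@dysregMultiplier < 0 || object@dysregMultiplier > 1)
        msg <- c(msg, "dysregMultiplier must lie in [0,1]")
    if (object@sigmaLE <= 0 || object@sigmaHE <= 0)
        msg <- c(msg, "mode standard deviations must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults mirror the emulated study: two replicates per condition, a
#' bimodal expressed-gene landscape (low mode near -2, high mode near 6 on
#' log2 FPKM), a planted regulated set with a slight excess of upregulated
#' genes, library sizes of 1e7-3e7 fragments and a dispersion trend
#' decreasing with mean expression.
#'
#' @param nGenes,conditions,nReplicates,piLE,muLE,sigmaLE,muHE,sigmaHE
#'   see \linkS4class{SimulationConfig}.
#' @param fracZero,nRegulated,fracUp,effectRange,mutantDysregulation see
#'   \linkS4class{SimulationConfig}.
#' @param dysregMultiplier,dispAlpha0,dispAlphaScale,dispAlphaMax see
#'   \linkS4class{SimulationConfig}.
#' @param librarySizeRange,geneLengthRange,seed see
#'   \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nGenes = 10000,
                             conditions = c("naive_th", "treg",
                                            "control", "foxp3",
                                            names(mutantDysregulation)),
                             nReplicates = 2L,
                             piLE = 0.5, muLE = -2, sigmaLE = 1,
                             muHE = 6, sigmaHE = 1,
                             fracZero = 0.1,
                             nRegulated = 1000L, fracUp = 0.52,
                             effectRange = c(2, 4),
                             mutantDysregulation = list(),
                             dysregMultiplier = 1,
                             dispAlpha0 = 0.05, dispAlphaScale = 2,
                             dispAlphaMax = 0.5,
                             librarySizeRange = c(1e7, 3e7),
                             geneLengthRange = c(500, 5000),
                             seed = 1L) {
    new("SimulationConfig", nGenes = as.integer(nGenes),
        conditions = unique(conditions),
        nReplicates = as.integer(nReplicates),
        piLE = piLE, muLE = muLE, sigmaLE = sigmaLE,
        muHE = muHE, sigmaHE = sigmaHE,
        fracZero = fracZero, nRegulated = as.integer(nRegulated),
        fracUp = fracUp, effectRange = as.numeric(effectRange),
        mutantDysregulation = mutantDysregulation,
        dysregMultiplier = dysregMultiplier,
        dispAlpha0 = dispAlpha0, dispAlphaScale = dispAlphaScale,
        dispAlphaMax = dispAlphaMax,
        librarySizeRange = as.numeric(librarySizeRange),
        geneLengthRange = as.numeric(geneLengthRange),
        seed = as.integer(seed))
}

#' Planted ground truth of a synthetic study
#'
#' @slot regulated gene identifiers of the planted regulated set.
#' @slot direction named character ("up"/"down"), one entry per regulated
#'   gene.
#' @slot dysregulated named list (one per mutant condition) of gene
#'   identifiers whose planted effect is reverted toward control; always
#'   subsets of \code{regulated}.
#' @slot trueMeans matrix of true mean log2 FPKM, genes x conditions
#'   (\code{-Inf} for all-zero genes).
#' @export
setClass("GroundTruth",
    representation(regulated = "character", direction = "character",
                   dysregulated = "list", trueMeans = "matrix"))

setValidity("GroundTruth", function(object) {
    msg <- character(0)
    if (!all(names(object@direction) == object@regulated))
        msg <- c(msg, "direction must be named by the regulated genes")
    for (s in object@dysregulated)
        if (!all(s %in% object@regulated))
            msg <- c(msg, "dysregulated sets must be subsets of the regulated set")
    if (length(msg)) unique(msg) else TRUE
})

#' @describeIn GroundTruth-class compact display.
#' @param object a \code{GroundTruth}.
#' @export
setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d regulated genes (%d up, %d down)\n",
                length(object@regulated),
                sum(object@direction == "up"),
                sum(object@direction == "down")))
    for (m in names(object@dysregulated))
        cat(sprintf("  %s: %d dysregulated\n", m,
                    length(object@dysregulated[[m]])))
})

#' A protein multiple sequence alignment with a designated reference
#'
#' Wraps an aligned \linkS4class{AAStringSet} (equal widths, gap '-') and the
#' identifier of the reference sequence in whose ungapped coordinates all
#' conservation profiles and subdomain segments are reported.
#'
#' @slot aln aligned sequences.
#' @slot refId name of the reference sequence.
#' @export
setClass("ProteinMSA",
    representation(aln = "AAStringSet", refId = "character"))

setValidity("ProteinMSA", function(object) {
    msg <- character(0)
    w <- Biostrings::width(object@aln)
    if (length(w) == 0 || length(unique(w)) != 1)
        msg <- c(msg, "all sequences must be aligned to equal length")
    if (!object@refId %in% names(object@aln))
        msg <- c(msg, "reference sequence absent from alignment")
    if (length(msg)) msg else TRUE
})

#' Construct a ProteinMSA
#' @param aln a named, aligned \code{AAStringSet} (or named character vector).
#' @param refId name of the reference sequence.
#' @export
ProteinMSA <- function(aln, refId) {
    if (is.character(aln)) aln <- Biostrings::AAStringSet(aln)
    new("ProteinMSA", aln = aln, refId = refId)
}

#' @describeIn ProteinMSA-class compact display.
#' @param object a \code{ProteinMSA}.
#' @export
setMethod("show", "ProteinMSA", function(object) {
    cat(sprintf("ProteinMSA: %d sequences, %d columns, reference '%s'\n",
                length(object@aln), Biostrings::width(object@aln)[1],
                object@refId))
})
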