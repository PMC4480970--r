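#' @importFrom IRanges IRanges start end width
#' @importFrom S4Vectors mcols mcols<-
NULL

# Column matrix of an alignment and the mapping of reference (ungapped)
# positions to alignment columns.
alnMatrix <- function(msa) {
    m <- do.call(rbind, strsplit(as.character(msa@aln), ""))
    rownames(m) <- names(msa@aln)
    m
}

refColumns <- function(msa) {
    m <- alnMatrix(msa)
    which(m[msa@refId, ] != "-")
}

#' Ungapped reference sequence of a ProteinMSA
#' @param msa a \linkS4class{ProteinMSA}.
#' @return single character string without gaps.
#' @export
refSequence <- function(msa) {
    gsub("-", "", as.character(msa@aln[[msa@refId]]))
}

#' Windowed average pairwise identity
#'
#' Per alignment column, the pairwise identity is the fraction of sequence
#' pairs with identical residues among the pairs in which neither sequence
#' has a gap (columns with fewer than two ungapped residues are undefined).
#' The profile is the centred moving average over \code{window} columns
#' (truncated at the ends, undefined columns renormalised out), reported at
#' the ungapped coordinates of the reference sequence.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param window moving-average width in columns (default 4).
#' @return numeric vector, one value per reference residue (names are the
#'   1-based reference positions).
#' @export
windowedIdentity <- function(msa, window = 4) {
    m <- alnMatrix(msa)
    if (window > ncol(m)) stop("window exceeds alignment length")
    colIdent <- apply(m, 2, function(col) {
        res <- col[col != "-"]
        n <- length(res)
        if (n < 2) return(NA_real_)
        tab <- table(res)
        sum(tab * (tab - 1) / 2) / (n * (n - 1) / 2)
    })
    prof <- movingAverage(colIdent, window)
    out <- prof[refColumns(msa)]
    names(out) <- seq_along(out)
    out
}

#' Windowed average pairwise similarity
#'
#' Per alignment column, the mean pairwise substitution-matrix score over
#' ungapped residue pairs, each score rescaled to [0,1] between the global
#' matrix minimum and the best score attainable by that pair (the larger of
#' the two diagonal entries, so identical residues always score exactly 1);
#' then a centred moving average over \code{window} columns, reported at
#' reference coordinates. The default matrix is BLOSUM62 restricted to the
#' 20 standard amino acids.
#'
#' @param msa a \linkS4class{ProteinMSA}.
#' @param window moving-average width in columns (default 20).
#' @param substitutionMatrix square numeric matrix with residue dimnames;
#'   defaults to BLOSUM62.
#' @return numeric vector over reference positions, values in [0,1].
#' @export
windowedSimilarity <- function(msa, window = 20,
                               substitutionMatrix = NULL) {
    if (is.null(substitutionMatrix)) {
        e <- new.env()
        utils::data("BLOSUM62", package = "Biostrings", envir = e)
        substitutionMatrix <- e$BLOSUM62
        aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
        substitutionMatrix <- substitutionMatrix[aa, aa]
    }
    mn <- min(substitutionMatrix)
    dg <- diag(substitutionMatrix)
    names(dg) <- rownames(substitutionMatrix)
    m <- alnMatrix(msa)
    if (window > ncol(m)) stop("window exceeds alignment length")
    colSim <- apply(m, 2, function(col) {
        res <- col[col != "-"]
        n <- length(res)
        if (n < 2) return(NA_real_)
        if (!all(res %in% rownames(substitutionMatrix)))
            stop("residue absent from the substitution matrix: ",
                 paste(setdiff(res, rownames(substitutionMatrix)),
                       collapse = ", "))
        pr <- utils::combn(res, 2)
        s <- substitutionMatrix[cbind(pr[1, ], pr[2, ])]
        top <- pmax(dg[pr[1, ]], dg[pr[2, ]])
        mean((s - mn) / (top - mn))
    })
    prof <- movingAverage(colSim, window)
    out <- prof[refColumns(msa)]
    names(out) <- seq_along(out)
    out
}

#' Sliding-window average of per-codon Bayes factors
#'
#' Centred moving average (default 4 codons) of a per-codon Bayes-factor
#' table in reference codon coordinates. Codons absent from the table are
#' treated as missing and renormalised out of their windows.
#'
#' @param bf a data.frame with columns \code{codon} (1-based index) and
#'   \code{bayes_factor}, or a numeric vector named by codon index.
#' @param window moving-average width in codons (default 4).
#' @return numeric vector over codons 1..max(codon).
#' @export
windowedBayes <- function(bf, window = 4) {
    if (is.data.frame(bf)) {
        idx <- as.integer(bf$codon)
        val <- as.numeric(bf$bayes_factor)
    } else {
        idx <- as.integer(names(bf))
        val <- as.numeric(bf)
    }
    if (length(idx) == 0 || all(is.na(val))) stop("all codons missing")
    if (any(idx < 1)) stop("codon indices must be 1-based")
    x <- rep(NA_real_, max(idx))
    x[idx] <- val
    prof <- movingAverage(x, window)
    names(prof) <- seq_along(prof)
    prof
}

#' Proline-framed subdomain segments of a reference sequence
#'
#' Maximal runs of non-proline residues between consecutive prolines (and
#' the sequence ends); zero-length runs between adjacent prolines are
#' omitted. Coordinates are 1-based inclusive positions of the ungapped
#' reference.
#'
#' @param referenceSequence character string (ungapped protein sequence) or
#'   a \linkS4class{ProteinMSA} (its reference is used).
#' @return an \linkS4class{IRanges} of segments.
#' @examples
#' prolineSegments("APLLPY")  # [1,1], [3,4], [6,6]
#' @export
prolineSegments <- function(referenceSequence) {
    if (is(referenceSequence, "ProteinMSA"))
        referenceSequence <- refSequence(referenceSequence)
    chars <- strsplit(referenceSequence, "")[[1]]
    if (length(chars) == 0) stop("empty sequence")
    nonP <- chars != "P"
    r <- rle(nonP)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    IRanges(start = starts[keep], end = ends[keep])
}

#' Annotate proline-framed segments with conservation and selection summaries
#'
#' Per segment, the means of the windowed identity, similarity and
#' Bayes-factor profiles over the segment interval; a segment is
#' \code{selected} when its mean Bayes factor exceeds \code{bfCutoff}
#' (evidence of purifying selection) and \code{conserved} when its mean
#' identity reaches \code{identityThreshold}.
#'
#' @param segments an \linkS4class{IRanges} from [prolineSegments()].
#' @param identityProfile,similarityProfile,bfProfile numeric vectors over
#'   reference positions (similarity and Bayes profiles may be NULL).
#' @param bfCutoff Bayes-factor cutoff (default 40).
#' @param identityThreshold identity level declaring a segment conserved
#'   (no universal default exists; choose per analysis).
#' @return the segments with metadata columns \code{meanIdentity},
#'   \code{meanSimilarity}, \code{meanBF}, \code{selected},
#'   \code{conserved}.
#' @export
annotateSegments <- function(segments, identityProfile,
                             similarityProfile = NULL, bfProfile = NULL,
                             bfCutoff = 40, identityThreshold = 0.8) {
    stopifnot(is(segments, "IRanges"))
    L <- length(identityProfile)
    if (length(segments) && max(end(segments)) > L)
        stop("segment outside profile range")
    segMean <- function(prof) {
        if (is.null(prof)) return(rep(NA_real_, length(segments)))
        if (max(end(segments)) > length(prof))
            stop("segment outside profile range")
        vapply(seq_along(segments), function(i) {
            mean(prof[start(segments)[i]:end(segments)[i]], na.rm = TRUE)
        }, numeric(1))
    }
    mcols(segments)$meanIdentity <- segMean(identityProfile)
    mcols(segments)$meanSimilarity <- segMean(similarityProfile)
    mcols(segments)$meanBF <- segMean(bfProfile)
    mcols(segments)$selected <- !is.na(mcols(segments)$meanBF) &
        mcols(segments)$meanBF > bfCutoff
    mcols(segments)$conserved <- !is.na(mcols(segments)$meanIdentity) &
        mcols(segments)$meanIdentity >= identityThreshold
    segments
}
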