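#' Exact two-sided binomial test
#'
#' Exact two-sided binomial p-value. The default minimum-likelihood
#' convention sums every binomial(n, p0) point mass not exceeding the mass
#' at the observed count (with the customary 1 + 1e-7 relative slack);
#' \code{convention = "double"} instead doubles the smaller tail. Point
#' masses are evaluated on the log scale internally, so p-values far below
#' 1e-300 do not underflow to spurious zeros.
#'
#' @param x number of successes (0..n).
#' @param n number of trials.
#' @param p0 null success probability, in (0,1).
#' @param convention "minlik" (default) or "double".
#' @return the p-value, capped at 1.
#' @examples
#' binomTwoSided(9, 10, 0.5)       # 0.021484375
#' binomTwoSided(1255, 2407, 0.5)  # ~0.0376
#' @export
binomTwoSided <- function(x, n, p0, convention = c("minlik", "double")) {
    convention <- match.arg(convention)
    if (length(x) != 1 || length(n) != 1 || is.na(x) || is.na(n) ||
        x < 0 || n < 1 || x > n || x != round(x) || n != round(n))
        stop("need integer 0 <= x <= n")
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
    if (convention == "double") {
        p <- 2 * min(stats::pbinom(x, n, p0),
                     stats::pbinom(x - 1, n, p0, lower.tail = FALSE))
        return(min(1, p))
    }
    logd <- stats::dbinom(0:n, n, p0, log = TRUE)
    cut <- logd[x + 1] + log(1 + 1e-7)
    min(1, sum(exp(logd[logd <= cut])))
}

#' Direction-split binomial test against a baseline
#'
#' Tests whether the split of factor-upregulated vs factor-downregulated
#' genes within a gene set differs from the split in the baseline regulated
#' set, by an exact two-sided binomial test of \code{nUp} successes in
#' \code{nUp + nDown} trials at null probability
#' \code{baselineUp / baselineTotal}.
#'
#' @param nUp,nDown counts of up- and downregulated genes in the set.
#' @param baselineUp,baselineTotal the reference split (e.g. 1255 of 2407).
#' @param convention passed to [binomTwoSided()].
#' @return the p-value.
#' @examples
#' directionDistributionTest(265, 129, 1255, 2407)  # ~1.5e-9
#' @export
directionDistributionTest <- function(nUp, nDown, baselineUp,
                                      baselineTotal,
                                      convention = "minlik") {
    if (nUp + nDown < 1) stop("empty gene set")
    if (baselineUp > baselineTotal || baselineTotal < 1)
        stop("invalid baseline split")
    binomTwoSided(nUp, nUp + nDown, baselineUp / baselineTotal,
                  convention = convention)
}

#' Exact two-sided Fisher test on a 2x2 table
#'
#' Two-sided Fisher exact p-value with margins fixed: the sum of all
#' hypergeometric point masses not exceeding the mass of the observed table
#' (with 1 + 1e-7 relative slack). Masses are computed on the log scale, so
#' enrichment p-values at the 1e-70 scale are returned without underflow.
#'
#' @param a,b,c,d the table counts (\code{a} successes in group 1, \code{b}
#'   failures in group 1, \code{c} successes in group 2, \code{d} failures
#'   in group 2).
#' @return the p-value, capped at 1.
#' @examples
#' fisher2x2(3, 1, 1, 3)  # 34/70
#' @export
fisher2x2 <- function(a, b, c, d) {
    v <- c(a, b, c, d)
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
        stop("table entries must be non-negative integers")
    if (sum(v) == 0) stop("all-zero table")
    m <- a + b          # group 1 size
    n <- c + d          # group 2 size
    kk <- a + c         # successes margin
    support <- max(0, kk - n):min(kk, m)
    logd <- stats::dhyper(support, m, n, kk, log = TRUE)
    cut <- logd[support == a] + log(1 + 1e-7)
    min(1, sum(exp(logd[logd <= cut])))
}

#' GO-term category distribution test
#'
#' Compares the split of immunology-related vs other enriched GO terms for a
#' gene list against the split observed for the full regulated gene set, by
#' an exact two-sided binomial test.
#'
#' @param nImmuno,nOther counts of immunology-related and other enriched
#'   terms in the list under test.
#' @param baselineImmuno,baselineOther the same counts for the full
#'   regulated set (e.g. 34 and 234).
#' @param convention passed to [binomTwoSided()].
#' @return the p-value.
#' @examples
#' goTermDistributionTest(26, 73, 34, 234)  # ~2.3e-4
#' @export
goTermDistributionTest <- function(nImmuno, nOther, baselineImmuno,
                                   baselineOther, convention = "minlik") {
    if (baselineImmuno + baselineOther < 1) stop("zero baseline")
    binomTwoSided(nImmuno, nImmuno + nOther,
                  baselineImmuno / (baselineImmuno + baselineOther),
                  convention = convention)
}

#' Euclidean distances between samples
#'
#' Pairwise Euclidean distances between sample columns of a log-transformed
#' normalised expression matrix (typically [regLog()] restricted to the
#' regulated genes).
#'
#' @param expr numeric matrix, genes x samples, no missing values.
#' @return symmetric distance matrix with zero diagonal.
#' @export
sampleDistances <- function(expr) {
    expr <- as.matrix(expr)
    if (any(!is.finite(expr))) stop("expression matrix has missing values")
    as.matrix(stats::dist(t(expr), method = "euclidean"))
}

#' PCA of sample transcriptomes
#'
#' Centred (unscaled) principal component analysis over samples.
#'
#' @param expr numeric matrix, genes x samples (>= 2 samples).
#' @return list with \code{scores} (samples x components),
#'   \code{rotation} (genes x components, orthonormal) and
#'   \code{varianceFraction} (summing to 1 over all components with
#'   positive variance).
#' @export
pcaSummary <- function(expr) {
    expr <- as.matrix(expr)
    if (ncol(expr) < 2) stop("need at least two samples")
    if (all(apply(expr, 1, stats::var) < 1e-24))
        stop("constant matrix: no variance to decompose")
    pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
    v <- pc$sdev^2
    list(scores = pc$x, rotation = pc$rotation,
         varianceFraction = v / sum(v))
}

#' Hierarchical clustering of samples
#'
#' Deterministic agglomerative clustering of a sample distance matrix.
#'
#' @param distMatrix symmetric distance matrix (or \code{dist}).
#' @param linkage agglomeration method, default complete linkage.
#' @return an \code{hclust} object.
#' @export
hierarchicalCluster <- function(distMatrix, linkage = "complete") {
    if (!inherits(distMatrix, "dist")) {
        m <- as.matrix(distMatrix)
        if (!isSymmetric(unname(m), tol = 1e-8))
            stop("distance matrix must be symmetric")
        distMatrix <- stats::as.dist(m)
    }
    n <- attr(distMatrix, "Size")
    if (n == 1) {     # a single sample clusters trivially
        return(structure(
            list(merge = matrix(integer(0), 0, 2), height = numeric(0),
                 order = 1L, labels = attr(distMatrix, "Labels"),
                 method = linkage, call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust"))
    }
    stats::hclust(distMatrix, method = linkage)
}
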