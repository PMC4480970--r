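#' Estimate per-gene negative-binomial dispersions
#'
#' A light-weight dispersion machinery for the NB Wald stage. Per gene, a
#' method-of-moments estimate is formed from normalised counts with
#' within-condition variances pooled across conditions,
#' \eqn{\hat\alpha = (s^2 - \bar\mu)/\bar\mu^2}; a smooth mean-dispersion
#' trend \eqn{\alpha_{tr}(\mu) = b_0 + b_1/\mu} is then fitted by regression
#' over well-expressed genes (using the untruncated moment statistic so the
#' trend stays unbiased), and the final dispersion is the per-gene estimate
#' shrunk toward the trend with weights given by the residual degrees of
#' freedom against the prior weight, floored at 1e-8. Genes with zero counts
#' in every sample are flagged untestable (NA dispersion).
#'
#' @param object a \linkS4class{FoxExperiment}; size factors are computed if
#'   absent. Every condition should have at least two replicates.
#' @param minMeanForTrend minimum mean normalised count for a gene to enter
#'   the trend regression.
#' @param priorDf prior degrees of freedom pulling per-gene estimates toward
#'   the trend. At two replicates per condition the per-gene moment
#'   estimates carry only a few residual degrees of freedom, so the default
#'   of 20 lets the trend dominate; raise the weight of the per-gene
#'   estimates only with deeper replication.
#' @return the object with \code{rowData()} columns \code{dispGeneEst},
#'   \code{dispFit}, \code{dispersion} and \code{untestable}.
#' @export
setMethod("estimateDispersions", "FoxExperiment",
    function(object, minMeanForTrend = 10, priorDf = 20, ...) {
    if (is.null(sizeFactors(object)))
        object <- computeSizeFactors(object)
    k <- counts(object)
    y <- sweep(k, 2, sizeFactors(object), "/")
    cond <- sampleConditions(object)
    tab <- table(cond)
    if (all(tab < 2))
        stop("dispersion estimation needs >= 2 replicates in some condition")

    n <- nrow(y)
    ssq <- numeric(n); df <- 0
    condMeanSum <- numeric(n); nCondUsed <- 0
    for (cc in names(tab)) {
        idx <- which(cond == cc)
        m <- rowMeans(y[, idx, drop = FALSE])
        condMeanSum <- condMeanSum + m
        nCondUsed <- nCondUsed + 1
        if (length(idx) < 2) next
        v <- rowSums((y[, idx, drop = FALSE] - m)^2) / (length(idx) - 1)
        ssq <- ssq + (length(idx) - 1) * v
        df <- df + (length(idx) - 1)
    }
    s2 <- ssq / df
    mu <- condMeanSum / nCondUsed
    untestable <- rowSums(k) == 0

    rawAlpha <- (s2 - mu) / mu^2           # untruncated, for the trend
    rawAlpha[untestable | mu == 0] <- NA
    geneEst <- pmax(rawAlpha, 0)

    use <- !is.na(rawAlpha) & mu >= minMeanForTrend & is.finite(rawAlpha)
    if (sum(use) >= 10) {
        co <- stats::coef(stats::lm(rawAlpha[use] ~ I(1 / mu[use])))
    } else {
        co <- c(mean(geneEst, na.rm = TRUE), 0)
    }
    dispFit <- pmax(co[1] + co[2] / mu, 1e-8)
    dispFit[untestable | mu == 0] <- NA

    dispersion <- pmax((df * geneEst + priorDf * dispFit) / (df + priorDf),
                       1e-8)
    rowData(object)$dispGeneEst <- geneEst
    rowData(object)$dispFit <- dispFit
    rowData(object)$dispersion <- dispersion
    rowData(object)$untestable <- untestable
    object
})

#' Negative-binomial Wald test with moderated log2 fold changes
#'
#' For one pairwise contrast, fits per-gene NB means for the two conditions
#' on size-factor-normalised counts with a zero-centred normal prior
#' (sd = \code{priorSD}) on the log2 fold change; the reported log2 fold
#' change is the posterior mode (moderated, never infinite). The Wald
#' statistic is the moderated log2 fold change divided by its sandwich
#' standard error (the curvature-corrected standard error of the penalised
#' estimator, built from the observed NB information at the penalised
#' optimum), referred to a standard normal, two-sided. P-values are adjusted
#' by Benjamini-Hochberg over the testable genes.
#'
#' @param object a \linkS4class{FoxExperiment} with dispersions estimated
#'   (run through [estimateDispersions()] automatically if not).
#' @param numerator,denominator condition labels; the log2 fold change is
#'   numerator over denominator.
#' @param priorSD standard deviation of the normal prior on log2fc; use
#'   \code{Inf} for the unshrunk maximum-likelihood fit.
#' @return a \linkS4class{DEResult} with columns \code{baseMean},
#'   \code{log2fc}, \code{se}, \code{stat}, \code{pvalue}, \code{padj},
#'   \code{dispersion}; contrast stored in \code{metadata()}.
#' @export
nbWaldTest <- function(object, numerator, denominator, priorSD = 2) {
    stopifnot(is(object, "FoxExperiment"))
    cond <- sampleConditions(object)
    for (cc in c(numerator, denominator))
        if (!cc %in% cond) stop("unknown condition: ", cc)
    if (!"dispersion" %in% colnames(rowData(object)))
        object <- estimateDispersions(object)
    sel <- cond %in% c(numerator, denominator)
    k <- counts(object)[, sel, drop = FALSE]
    sf <- sizeFactors(object)[sel]
    x <- as.numeric(cond[sel] == numerator)   # 1 = numerator samples
    alpha <- rowData(object)$dispersion
    testable <- rowSums(k) > 0

    fit <- nbFitContrast(k[testable, , drop = FALSE], sf, x,
                         alpha[testable], priorSD)

    n <- nrow(object)
    out <- DataFrame(
        baseMean = rowMeans(sweep(k, 2, sf, "/")),
        log2fc = rep(NA_real_, n), se = rep(NA_real_, n),
        stat = rep(NA_real_, n), pvalue = rep(NA_real_, n),
        padj = rep(NA_real_, n),
        dispersion = alpha,
        row.names = rownames(object))
    out$log2fc[testable] <- fit$b
    out$se[testable] <- fit$se
    out$stat[testable] <- fit$z
    out$pvalue[testable] <- fit$p
    out$padj <- bhAdjust(out$pvalue)
    res <- new("DEResult", out)
    metadata(res) <- list(numerator = numerator,
                          denominator = denominator, priorSD = priorSD)
    res
}

# Vectorised Fisher-scoring fit of the 2-parameter model
#   log2 mu_ij = a_g + b_g * x_j  (+ log2 size factor offset)
# with an optional ridge penalty b^2/(2 sigma^2), across all genes at once.
nbFitContrast <- function(k, sf, x, alpha, priorSD,
                          maxIter = 60L, tol = 1e-10) {
    ln2 <- log(2)
    lam <- if (is.finite(priorSD)) 1 / priorSD^2 else 0
    nG <- nrow(k)
    i1 <- x == 1; i0 <- !i1
    eps <- 0.125
    m1 <- rowMeans(sweep(k[, i1, drop = FALSE], 2, sf[i1], "/"))
    m0 <- rowMeans(sweep(k[, i0, drop = FALSE], 2, sf[i0], "/"))
    a <- log2(m0 + eps)
    b <- log2(m1 + eps) - a

    penll <- function(a, b) {
        eta <- outer(a, rep(1, length(x))) + outer(b, x)
        mu <- sweep(2^eta, 2, sf, "*")
        size <- 1 / alpha
        ll <- rowSums(stats::dnbinom(k, mu = mu, size = size, log = TRUE))
        ll - lam * b^2 / 2
    }
    obj <- penll(a, b)
    for (iter in seq_len(maxIter)) {
        eta <- outer(a, rep(1, length(x))) + outer(b, x)
        mu <- sweep(2^eta, 2, sf, "*")
        w <- (k - mu) / (1 + alpha * mu)          # score contributions
        info <- mu / (1 + alpha * mu)             # expected information
        ga <- ln2 * rowSums(w)
        gb <- ln2 * rowSums(w[, i1, drop = FALSE]) - lam * b
        S <- ln2^2 * rowSums(info)
        S1 <- ln2^2 * rowSums(info[, i1, drop = FALSE])
        det <- S * (S1 + lam) - S1 * S1
        det <- pmax(det, 1e-12)
        da <- ((S1 + lam) * ga - S1 * gb) / det
        db <- (S * gb - S1 * ga) / det
        # step-halving against the penalised objective
        stepScale <- rep(1, nG)
        for (h in 1:8) {
            newObj <- penll(a + stepScale * da, b + stepScale * db)
            bad <- newObj < obj - 1e-10
            if (!any(bad)) break
            stepScale[bad] <- stepScale[bad] / 2
        }
        a <- a + stepScale * da
        b <- b + stepScale * db
        newObj <- penll(a, b)
        moved <- max(abs(c(stepScale * da, stepScale * db)))
        obj <- newObj
        if (moved < tol) break
    }

    # sandwich SE of the penalised estimator from the observed information
    eta <- outer(a, rep(1, length(x))) + outer(b, x)
    mu <- sweep(2^eta, 2, sf, "*")
    iobs <- mu * (1 + alpha * k) / (1 + alpha * mu)^2
    S <- ln2^2 * rowSums(iobs)
    S1 <- ln2^2 * rowSums(iobs[, i1, drop = FALSE])
    # H_ll = [[S, S1], [S1, S1]], H_g = H_ll + diag(0, lam)
    # V = H_g^{-1} H_ll H_g^{-1}; se(b) = sqrt(V[2,2])
    det <- pmax(S * (S1 + lam) - S1 * S1, 1e-12)
    # row of H_g^{-1} for b: (-S1, S) / det
    vbb <- (S1 * S1 * S - 2 * S1 * S * S1 + S * S * S1) / det^2
    se <- sqrt(pmax(vbb, 1e-300))
    z <- b / se
    p <- 2 * stats::pnorm(-abs(z))
    list(a = a, b = b, se = se, z = z, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the defined p-values; NA entries (untestable
#' genes) are passed through unchanged and do not count toward the number of
#' tests.
#'
#' @param p numeric vector of p-values in [0,1], NA allowed.
#' @return adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0,1]")
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- stats::p.adjust(p[ok], method = "BH")
    out
}
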