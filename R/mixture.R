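#' Fit a two-component Gaussian mixture to log2-FPKM values by EM
#'
#' Expectation-maximisation for an unequal-variance two-component Gaussian
#' mixture, as used to separate the lowly-expressed (LE) and
#' highly-expressed (HE) modes of the log2-FPKM distribution of expressed
#' genes in one sequencing replicate. Non-expressed (NE, zero-count) genes
#' must be removed before fitting. The fit is restarted from a median-split
#' initialisation plus \code{nRestarts} random initialisations drawn from a
#' fixed internal substream, and the run with the best log-likelihood is
#' kept; components are reported ordered by mean, so label switching cannot
#' occur.
#'
#' @param values finite numeric vector (log2 FPKM of expressed genes);
#'   at least 50 values.
#' @param maxIter maximum EM iterations per start.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param nRestarts number of random restarts besides the median split.
#' @param restartSeed seed of the restart substream (fixed for
#'   reproducibility; does not disturb the caller's RNG).
#' @return a \linkS4class{MixtureFit}.
#' @examples
#' x <- c(rnorm(500, -2), rnorm(500, 6))
#' fitBimodal(x)
#' @export
fitBimodal <- function(values, maxIter = 1000L, tol = 1e-8,
                       nRestarts = 5L, restartSeed = 20150521L) {
    x <- values[is.finite(values)]
    if (length(x) < 50)
        stop("need at least 50 finite values to fit the mixture")
    if (stats::sd(x) < 1e-12)
        stop("unimodal/degenerate input: all values identical")

    starts <- list(medianSplitStart(x))
    starts <- c(starts, withSeed(restartSeed, {
        lapply(seq_len(nRestarts), function(i) randomStart(x))
    }))

    best <- NULL
    for (st in starts) {
        fit <- emGaussian2(x, st, maxIter = maxIter, tol = tol)
        if (is.null(fit)) next
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    if (is.null(best))
        stop("unimodal/degenerate input: EM failed from every start")

    ord <- order(best$mu)
    new("MixtureFit",
        piLE = best$pi[ord[1]], piHE = best$pi[ord[2]],
        muLE = best$mu[ord[1]], muHE = best$mu[ord[2]],
        sigmaLE = best$sigma[ord[1]], sigmaHE = best$sigma[ord[2]],
        logLik = best$loglik, logLikTrace = best$trace,
        nPoints = length(x), converged = best$converged)
}

# Split at the median: moment-match each half.
medianSplitStart <- function(x) {
    m <- stats::median(x)
    lo <- x[x <= m]; hi <- x[x > m]
    list(pi = c(length(lo), length(hi)) / length(x),
         mu = c(mean(lo), mean(hi)),
         sigma = pmax(c(stats::sd(lo), stats::sd(hi)),
                      0.05 * stats::sd(x), 1e-3))
}

randomStart <- function(x) {
    q <- stats::quantile(x, sort(stats::runif(2, 0.1, 0.9)))
    s <- stats::sd(x)
    list(pi = { p <- stats::runif(1, 0.2, 0.8); c(p, 1 - p) },
         mu = as.numeric(q),
         sigma = stats::runif(2, 0.2, 1) * s)
}

# One EM run. Returns NULL if the run degenerates (component collapse).
emGaussian2 <- function(x, start, maxIter, tol) {
    n <- length(x)
    pi_ <- start$pi; mu <- start$mu; sigma <- start$sigma
    sigmaFloor <- max(1e-6, 1e-3 * stats::sd(x))
    trace <- numeric(0)
    ll <- -Inf
    converged <- FALSE
    for (iter in seq_len(maxIter)) {
        d1 <- pi_[1] * stats::dnorm(x, mu[1], sigma[1])
        d2 <- pi_[2] * stats::dnorm(x, mu[2], sigma[2])
        tot <- d1 + d2
        if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
        newll <- sum(log(tot))
        trace <- c(trace, newll)
        if (is.finite(ll) && newll - ll < tol && newll >= ll - 1e-9) {
            ll <- newll
            converged <- TRUE
            break
        }
        ll <- newll
        g <- d1 / tot                     # responsibility of component 1
        n1 <- sum(g); n2 <- n - n1
        if (n1 < 2 || n2 < 2) return(NULL)
        mu[1] <- sum(g * x) / n1
        mu[2] <- sum((1 - g) * x) / n2
        sigma[1] <- sqrt(sum(g * (x - mu[1])^2) / n1)
        sigma[2] <- sqrt(sum((1 - g) * (x - mu[2])^2) / n2)
        sigma <- pmax(sigma, sigmaFloor)
        pi_ <- c(n1, n2) / n
        pi_ <- pmin(pmax(pi_, 1e-6), 1 - 1e-6)
    }
    if (abs(mu[1] - mu[2]) < 1e-8) return(NULL)
    list(pi = pi_, mu = mu, sigma = sigma, loglik = ll, trace = trace,
         converged = converged)
}

#' LE/HE class boundaries at a target FDR
#'
#' Derives the log2-FPKM thresholds delimiting the LE and HE expression
#' classes from a mixture fit. With the default tail-overlap method, the HE
#' boundary is the smallest \eqn{x} at which the expected fraction of
#' LE-component genes among all genes above \eqn{x} (the tail FDR)
#' \deqn{\mathrm{FDR}_{HE}(x) = \frac{\pi_{LE}(1-\Phi_{LE}(x))}
#'   {\pi_{LE}(1-\Phi_{LE}(x)) + \pi_{HE}(1-\Phi_{HE}(x))}}
#' drops to \code{fdr}, and symmetrically the LE boundary is the largest
#' \eqn{x} at which the HE contamination below \eqn{x} is at most
#' \code{fdr}. Both are found by monotone bisection to an absolute tolerance
#' of 1e-6. With \code{method = "posterior"} the local posterior probability
#' of the opposite component replaces the tail ratio. When the components
#' are so separated that the constraint holds everywhere between the means
#' (so the two thresholds would cross), both bounds are placed at the
#' crossing of the two scaled component densities and the result is flagged
#' degenerate.
#'
#' @param fit a \linkS4class{MixtureFit}.
#' @param fdr target false discovery rate for each called class.
#' @param method "tail" (default) or "posterior".
#' @return a \linkS4class{ClassBoundaries}.
#' @export
classBoundaries <- function(fit, fdr = 0.05,
                            method = c("tail", "posterior")) {
    method <- match.arg(method)
    stopifnot(is(fit, "MixtureFit"), fdr > 0, fdr < 1)
    piL <- fit@piLE; piH <- fit@piHE
    muL <- fit@muLE; muH <- fit@muHE
    sL <- fit@sigmaLE; sH <- fit@sigmaHE

    fdrHE <- function(x) {          # decreasing in x
        a <- piL * stats::pnorm(x, muL, sL, lower.tail = FALSE)
        b <- piH * stats::pnorm(x, muH, sH, lower.tail = FALSE)
        if (method == "tail") a / (a + b)
        else piL * stats::dnorm(x, muL, sL) /
            (piL * stats::dnorm(x, muL, sL) +
             piH * stats::dnorm(x, muH, sH))
    }
    fdrLE <- function(x) {          # increasing in x
        a <- piL * stats::pnorm(x, muL, sL)
        b <- piH * stats::pnorm(x, muH, sH)
        if (method == "tail") b / (a + b)
        else piH * stats::dnorm(x, muH, sH) /
            (piL * stats::dnorm(x, muL, sL) +
             piH * stats::dnorm(x, muH, sH))
    }

    lo <- muL - 8 * sL
    hi <- muH + 8 * sH
    tHE <- bisectThreshold(fdrHE, lo, hi, fdr, decreasing = TRUE)
    tLE <- bisectThreshold(fdrLE, lo, hi, fdr, decreasing = FALSE)

    degenerate <- is.na(tHE) || is.na(tLE) || tLE > tHE
    if (degenerate) {
        cross <- densityCrossing(piL, muL, sL, piH, muH, sH)
        tLE <- tHE <- cross
    }
    new("ClassBoundaries", tLE = tLE, tHE = tHE, fdr = fdr,
        method = method, degenerate = degenerate)
}

# Smallest (decreasing f) or largest (increasing f) x in [lo, hi] with
# f(x) <= level; NA when the constraint holds over the whole interval
# already at the inner end, or can never be met.
bisectThreshold <- function(f, lo, hi, level, decreasing, tol = 1e-6) {
    if (decreasing) {
        if (f(lo) <= level) return(NA_real_)   # satisfied everywhere
        if (f(hi) > level) return(NA_real_)    # never satisfied
    } else {
        if (f(hi) <= level) return(NA_real_)
        if (f(lo) > level) return(NA_real_)
    }
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        sat <- f(mid) <= level
        if (decreasing) { if (sat) hi <- mid else lo <- mid }
        else            { if (sat) lo <- mid else hi <- mid }
    }
    (lo + hi) / 2
}

# Crossing of the two weight-scaled component densities between the means.
densityCrossing <- function(piL, muL, sL, piH, muH, sH) {
    h <- function(x) log(piL) + stats::dnorm(x, muL, sL, log = TRUE) -
        log(piH) - stats::dnorm(x, muH, sH, log = TRUE)
    if (h(muL) <= 0 || h(muH) >= 0) return((muL + muH) / 2)
    stats::uniroot(h, c(muL, muH), tol = 1e-9)$root
}

#' Classify genes into NE/LE/INT/HE expression classes per replicate
#'
#' For every sample independently: genes with zero counts are NE; for the
#' remaining genes a two-component Gaussian mixture is fitted to the log2
#' FPKM values ([fitBimodal()]) and FDR boundaries derived
#' ([classBoundaries()]); log2 FPKM at or below the LE bound gives LE, at or
#' above the HE bound gives HE, and values strictly between are INT.
#'
#' @param object a \linkS4class{FoxExperiment}.
#' @param fdr FDR level for the class boundaries.
#' @param method boundary method, see [classBoundaries()].
#' @param ... further arguments passed to [fitBimodal()].
#' @return the object with a character \code{"class"} assay added and the
#'   per-sample fits and boundaries stored in
#'   \code{metadata()$mixtureFits} / \code{metadata()$classBoundaries}.
#' @export
classifyGenes <- function(object, fdr = 0.05, method = "tail", ...) {
    stopifnot(is(object, "FoxExperiment"))
    if (!"log2fpkm" %in% assayNames(object))
        object <- computeFPKM(object)
    lf <- assay(object, "log2fpkm")
    k <- counts(object)
    cls <- matrix(NA_character_, nrow(object), ncol(object),
                  dimnames = dimnames(k))
    fits <- vector("list", ncol(object))
    bounds <- vector("list", ncol(object))
    names(fits) <- names(bounds) <- colnames(object)
    for (j in seq_len(ncol(object))) {
        expressed <- k[, j] > 0
        fit <- fitBimodal(lf[expressed, j], ...)
        bd <- classBoundaries(fit, fdr = fdr, method = method)
        lab <- rep("INT", nrow(object))
        lab[lf[, j] <= bd@tLE] <- "LE"
        lab[lf[, j] >= bd@tHE] <- "HE"
        lab[!expressed] <- "NE"
        cls[, j] <- lab
        fits[[j]] <- fit
        bounds[[j]] <- bd
    }
    assay(object, "class") <- cls
    metadata(object)$mixtureFits <- fits
    metadata(object)$classBoundaries <- bounds
    metadata(object)$classFdr <- fdr
    object
}
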