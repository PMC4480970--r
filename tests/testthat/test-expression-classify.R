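test_that("median-of-ratios size factors follow the geometric-mean rule", {
    k <- matrix(c(10, 20, 30, 40, 20, 40, 60, 80), ncol = 2)
    expect_equal(unname(computeSizeFactors(k)),
                 c(1 / sqrt(2), sqrt(2)))
    # identical samples
    expect_equal(unname(computeSizeFactors(cbind(1:5 * 10, 1:5 * 10))),
                 c(1, 1))
    # a gene with a zero anywhere is excluded from the reference set:
    # corrupting it must not move the factors
    k2 <- k; k2[1, 1] <- 0
    k3 <- k[-1, ]
    expect_equal(unname(computeSizeFactors(k2)),
                 unname(computeSizeFactors(k3)))
    expect_error(computeSizeFactors(matrix(c(0, 1, 1, 0), 2)),
                 "cannot form reference")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
    set.seed(10)
    k <- matrix(rnbinom(400 * 6, mu = 200, size = 5) + 1, ncol = 6)
    mine <- unname(computeSizeFactors(k))
    ref <- unname(DESeq2::estimateSizeFactorsForMatrix(k))
    expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("FPKM follows the normalised formula and its invariances", {
    # single sample, length 1 kb, count 100, column total 1e6 -> FPKM 100
    k <- matrix(c(100, 1e6 - 100), ncol = 1,
                dimnames = list(c("g1", "g2"), "s1"))
    fe <- FoxExperiment(k, geneLengths = c(1000, 1000), condition = "a")
    fe <- computeFPKM(fe, sf = 1)
    expect_equal(unname(assay(fe, "fpkm")["g1", 1]), 100)

    # zero counts map to zero FPKM regardless of length
    k2 <- matrix(c(0L, 50L, 10L, 60L), ncol = 2)
    fe2 <- FoxExperiment(k2, geneLengths = c(123, 4567),
                         condition = c("a", "a"))
    fe2 <- computeFPKM(fe2, sf = c(1, 1))
    expect_equal(unname(assay(fe2, "fpkm")[1, 1]), 0)

    # doubling one sample's counts leaves its FPKM column unchanged
    set.seed(4)
    k3 <- matrix(rpois(300, 100) + 1, ncol = 3)
    fe3 <- computeFPKM(FoxExperiment(k3, rep(500, 100), rep("a", 3)))
    k4 <- k3; k4[, 2] <- 2L * k4[, 2]
    fe4 <- computeFPKM(FoxExperiment(k4, rep(500, 100), rep("a", 3)))
    expect_equal(assay(fe3, "fpkm"), assay(fe4, "fpkm"),
                 tolerance = 1e-12, ignore_attr = TRUE)

    fe5 <- FoxExperiment(k2, geneLengths = c(123, 4567),
                         condition = c("a", "a"))
    SummarizedExperiment::rowData(fe5)$gene_length[1] <- NA
    expect_error(computeFPKM(fe5, sf = c(1, 1)), "positive length")
})

test_that("EM recovers a planted bimodal mixture and is label-stable", {
    set.seed(7)
    x <- c(rnorm(1200, -2, 1), rnorm(800, 6, 1))
    fit <- fitBimodal(x)
    expect_lt(abs(fit@muLE - (-2)), 0.15)
    expect_lt(abs(fit@muHE - 6), 0.15)
    expect_lt(abs(fit@piLE - 0.6), 0.03)
    expect_true(fit@muLE < fit@muHE)           # ordering post-condition
    # log-likelihood is non-decreasing across EM iterations
    expect_true(all(diff(fit@logLikTrace) > -1e-6))
    expect_error(fitBimodal(rep(1, 100)), "degenerate")
    expect_error(fitBimodal(rnorm(20)), "at least 50")
})

test_that("EM matches the mclust oracle on a planted mixture", {
    withr::local_package("mclust")
    set.seed(8)
    x <- c(rnorm(1000, -1.5, 0.8), rnorm(1000, 5, 1.4))
    fit <- fitBimodal(x)
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    mcMu <- sort(mc$parameters$mean)
    expect_lt(abs(fit@muLE - mcMu[1]), 0.1)
    expect_lt(abs(fit@muHE - mcMu[2]), 0.1)
    expect_lt(abs(fit@logLik - mc$loglik), 1)
})

test_that("FDR class boundaries obey the tail definitions", {
    fit <- new("MixtureFit", piLE = 0.5, piHE = 0.5, muLE = -2, muHE = 6,
               sigmaLE = 1, sigmaHE = 1, logLik = 0, logLikTrace = 0,
               nPoints = 100L, converged = TRUE)
    bd <- classBoundaries(fit, 0.05)
    # tail FDR at x = 2 is ~3.2e-5, far below 0.05, so tHE <= 2; with this
    # separation the constraint holds everywhere between the means and the
    # boundary collapses to the density crossing at 2 (flagged degenerate)
    expect_lte(bd@tHE, 2 + 1e-6)
    expect_true(bd@degenerate)
    expect_equal(bd@tHE, 2, tolerance = 1e-6)
    expect_lte(bd@tLE, bd@tHE)

    # overlapping components: genuine INT zone, monotone in fdr
    fit2 <- new("MixtureFit", piLE = 0.6, piHE = 0.4, muLE = 0, muHE = 3,
                sigmaLE = 1.2, sigmaHE = 1.1, logLik = 0, logLikTrace = 0,
                nPoints = 100L, converged = TRUE)
    b05 <- classBoundaries(fit2, 0.05)
    b01 <- classBoundaries(fit2, 0.01)
    expect_false(b05@degenerate)
    expect_lt(b05@tLE, b05@tHE)
    expect_gte(b01@tHE, b05@tHE)
    expect_lte(b01@tLE, b05@tLE)
    # the realised tail FDR at the boundary equals the target
    tailFdrHE <- function(x) {
        a <- 0.6 * pnorm(x, 0, 1.2, lower.tail = FALSE)
        b <- 0.4 * pnorm(x, 3, 1.1, lower.tail = FALSE)
        a / (a + b)
    }
    expect_equal(tailFdrHE(b05@tHE), 0.05, tolerance = 1e-3)
    # posterior variant also produces ordered boundaries
    bp <- classBoundaries(fit2, 0.05, method = "posterior")
    expect_lte(bp@tLE, bp@tHE)
})

test_that("classification is NE at zero counts and monotone in FPKM", {
    cfg <- SimulationConfig(nGenes = 2000, nRegulated = 0, fracZero = 0.1,
                            conditions = c("naive_th", "treg", "control",
                                           "foxp3"),
                            seed = 6L)
    sim <- simulateCounts(cfg)
    fox <- classifyGenes(computeFPKM(computeSizeFactors(sim$experiment)))
    cls <- expressionClasses(fox)
    k <- counts(fox)
    expect_true(all((cls == "NE") == (k == 0)))
    # monotone: within each sample, ordering classes by FPKM never inverts
    lf <- assay(fox, "log2fpkm")
    rank <- matrix(match(cls, c("NE", "LE", "INT", "HE")), nrow(cls))
    for (j in c(1, 5)) {
        ord <- order(lf[, j])
        expect_true(all(diff(rank[ord, j]) >= 0))
    }
})
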