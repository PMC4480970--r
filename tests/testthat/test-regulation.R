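# Hand-built miniature experiment for the rule logic: classes and DE
# results are constructed directly so each clause of the caller can be
# exercised in isolation.
makeRuleFixture <- function() {
    genes <- paste0("g", 1:6)
    cond <- rep(c("naive_th", "treg", "control", "foxp3", "mutA"), each = 2)
    k <- matrix(50L, 6, 10, dimnames = list(genes, paste0(cond, "_r",
                                                          rep(1:2, 5))))
    fox <- FoxExperiment(k, rep(1000, 6), cond)
    sizeFactors(fox) <- rep(1, 10)
    cls <- matrix("HE", 6, 10, dimnames = dimnames(k))
    cls[2, ] <- "LE"                     # g2: never above LE anywhere
    assay(fox, "class", withDimnames = FALSE) <- cls
    fox
}

makeDE <- function(genes, lfc, padj, numerator, denominator) {
    d <- S4Vectors::DataFrame(
        baseMean = rep(100, length(genes)), log2fc = lfc,
        se = rep(0.1, length(genes)), stat = lfc / 0.1,
        pvalue = padj, padj = padj,
        dispersion = rep(0.1, length(genes)), row.names = genes)
    res <- new("DEResult", d)
    S4Vectors::metadata(res) <- list(numerator = numerator,
                                     denominator = denominator,
                                     priorSD = 2)
    res
}

test_that("differential calls require both significance and expression", {
    fox <- makeRuleFixture()
    genes <- rownames(fox)
    de <- makeDE(genes, lfc = c(2, 2, 2, -2, 0.1, 2),
                 padj = c(0.01, 0.01, 0.06, 0.01, 0.01, NA),
                 "foxp3", "control")
    d <- callDifferential(de, fox)
    expect_true(d[["g1"]])      # significant and HE
    expect_false(d[["g2"]])     # significant but NE/LE in both conditions
    expect_false(d[["g3"]])     # padj above threshold
    expect_false(d[["g6"]])     # untestable
})

test_that("regulated genes are the intersection of both contrasts with
           direction from the factor contrast", {
    fox <- makeRuleFixture()
    genes <- rownames(fox)
    deL <- makeDE(genes, lfc = c(2, 2, 2, -2, 2, 2),
                  padj = c(0.01, 0.01, 0.01, 0.01, 0.2, 0.01),
                  "treg", "naive_th")
    deF <- makeDE(genes, lfc = c(2, 2, 2, -2, 2, 0.5),
                  padj = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01),
                  "foxp3", "control")
    reg <- callFoxp3Regulated(deL, deF, fox)
    expect_equal(rownames(reg)[reg$regulated], c("g1", "g4", "g6"))
    expect_equal(reg["g1", "direction"], "up")
    expect_equal(reg["g4", "direction"], "down")
    expect_true(is.na(reg["g3", "direction"]))
})

test_that("mutant status applies the toward-control direction rule", {
    fox <- makeRuleFixture()
    genes <- rownames(fox)
    deL <- makeDE(genes, rep(2, 6), rep(0.01, 6), "treg", "naive_th")
    deF <- makeDE(genes, c(2, 2, 2, -2, 2, 2), rep(0.01, 6),
                  "foxp3", "control")
    reg <- callFoxp3Regulated(deL, deF, fox)
    # mutant contrast is mutant vs foxp3
    deM <- makeDE(genes,
                  lfc = c(-2,   -2,  2,    2,   -0.1, 0.1),
                  padj = c(0.01, 0.01, 0.01, 0.01, 0.6, 0.6),
                  "mutA", "foxp3")
    reg <- callMutantStatus(reg, deM, fox)
    st <- reg$status_mutA
    names(st) <- genes
    # g1: factor-up gene, mutant significantly below foxp3 -> toward
    # control -> dysregulated
    expect_equal(st[["g1"]], "dysregulated")
    # g2: not regulated (failed class filter) -> untested
    expect_equal(st[["g2"]], "untested")
    # g3: factor-up gene, mutant significantly ABOVE foxp3 (enhanced
    # regulation) -> retained
    expect_equal(st[["g3"]], "retained")
    # g4: factor-down gene, mutant significantly above foxp3 -> toward
    # control -> dysregulated
    expect_equal(st[["g4"]], "dysregulated")
    # g5: no significant change -> retained
    expect_equal(st[["g5"]], "retained")

    # flipped orientation (foxp3 vs mutant) gives identical calls
    deM2 <- makeDE(genes,
                   lfc = -c(-2, -2, 2, 2, -0.1, 0.1),
                   padj = c(0.01, 0.01, 0.01, 0.01, 0.6, 0.6),
                   "foxp3", "mutA")
    reg2 <- callMutantStatus(callFoxp3Regulated(deL, deF, fox), deM2, fox)
    expect_equal(reg2$status_mutA, reg$status_mutA)

    s <- summarizeSets(reg)
    expect_equal(s$perMutant$dysUp + s$perMutant$dysDown,
                 s$perMutant$dysregulated)
    expect_true(all(s$dysregulatedSets$mutA %in%
                        rownames(reg)[reg$regulated]))
})

test_that("end-to-end calls recover planted regulation with high overlap", {
    cfg <- SimulationConfig(nGenes = 2000, nRegulated = 200,
                            mutantDysregulation = list(mutA = 1:40,
                                                       mutB = 41:50),
                            seed = 16L)
    sim <- simulateCounts(cfg)
    fox <- classifyGenes(computeFPKM(computeSizeFactors(sim$experiment)))
    fox <- estimateDispersions(fox)
    reg <- callFoxp3Regulated(nbWaldTest(fox, "treg", "naive_th"),
                              nbWaldTest(fox, "foxp3", "control"), fox)
    called <- rownames(reg)[reg$regulated]
    planted <- sim$truth@regulated
    jac <- length(intersect(called, planted)) /
        length(union(called, planted))
    expect_gte(jac, 0.9)

    for (m in c("mutA", "mutB"))
        reg <- callMutantStatus(reg, nbWaldTest(fox, m, "foxp3"), fox)
    s <- summarizeSets(reg)
    for (m in c("mutA", "mutB")) {
        a <- s$dysregulatedSets[[m]]
        b <- sim$truth@dysregulated[[m]]
        expect_gte(length(intersect(a, b)) / length(union(a, b)), 0.8)
        expect_true(all(a %in% called))
    }
    # disjoint planted sets stay essentially disjoint in the calls
    expect_lte(s$intersections["mutA", "mutB"], 2)

    # caller is invariant to gene order
    perm <- sample(nrow(fox))
    foxP <- fox[perm, ]
    regP <- callFoxp3Regulated(nbWaldTest(foxP, "treg", "naive_th"),
                               nbWaldTest(foxP, "foxp3", "control"), foxP)
    expect_setequal(rownames(regP)[regP$regulated], called)
})
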