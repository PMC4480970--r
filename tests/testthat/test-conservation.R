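test_that("windowed identity follows the pair-counting definition", {
    msa <- ProteinMSA(c(ref = "ACDE", s1 = "ACDF"), "ref")
    prof <- windowedIdentity(msa, 4)
    # full window at position 2 covers all four columns: 3/4 identical
    expect_equal(unname(prof[2]), 0.75)
    # identical sequences: identity 1 everywhere
    same <- ProteinMSA(c(ref = "MKLV", a = "MKLV", b = "MKLV"), "ref")
    expect_true(all(windowedIdentity(same, 2) == 1))
    expect_error(windowedIdentity(msa, 10), "window exceeds")

    # gapped pairs are excluded from the per-column denominator
    gapped <- ProteinMSA(c(ref = "AC", s1 = "A-", s2 = "AG"), "ref")
    prof2 <- windowedIdentity(gapped, 1)
    expect_equal(unname(prof2[1]), 1)        # three identical 'A's
    expect_equal(unname(prof2[2]), 0)        # single C/G pair, mismatch

    # two-sequence closed form: identity = 1 - windowed Hamming fraction
    set.seed(21)
    s1 <- paste(sample(LETTERS[1:5], 60, TRUE), collapse = "")
    s2 <- paste(sample(LETTERS[1:5], 60, TRUE), collapse = "")
    msa2 <- ProteinMSA(c(ref = s1, other = s2), "ref")
    prof3 <- windowedIdentity(msa2, 5)
    ham <- as.integer(strsplit(s1, "")[[1]] != strsplit(s2, "")[[1]])
    csum <- c(0, cumsum(ham))
    expect_equal(unname(prof3[10]),
                 1 - (csum[13] - csum[8]) / 5)    # window 8..12 at pos 10
})

test_that("column identity matches pair enumeration and responds
           monotonically to consensus duplication", {
    set.seed(22)
    for (trial in 1:5) {
        n <- 5; L <- 30
        rows <- replicate(n, paste(sample(c(LETTERS[1:4], "-"), L, TRUE,
                                          prob = c(rep(0.22, 4), 0.12)),
                                   collapse = ""))
        names(rows) <- c("ref", paste0("s", 1:(n - 1)))
        rows["ref"] <- gsub("-", "A", rows["ref"])
        msa <- ProteinMSA(rows, "ref")
        # the profile is invariant to sequence order
        shuf <- ProteinMSA(rows[c(1, sample(2:n))], "ref")
        expect_equal(windowedIdentity(shuf, 3), windowedIdentity(msa, 3))
        # column identity agrees with explicit pair enumeration
        mat <- do.call(rbind, strsplit(unname(rows), ""))
        expect_equal(unname(windowedIdentity(msa, 1)),
                     unname(pairEnumerationIdentity(mat)[
                         mat[1, ] != "-"]))
        # duplicating a column consensus residue never decreases that
        # column's identity (duplicating a minority residue may, so the
        # guarantee is per consensus, checked against enumeration)
        cons <- apply(mat, 2, function(col) {
            res <- col[col != "-"]
            if (!length(res)) "-" else names(sort(table(res),
                                                  decreasing = TRUE))[1]
        })
        dup <- ProteinMSA(c(rows, dup = paste(cons, collapse = "")),
                          "ref")
        a <- windowedIdentity(msa, 1)
        b <- windowedIdentity(dup, 1)
        ok <- !is.na(a) & !is.na(b)
        expect_true(all(b[ok] >= a[ok] - 1e-12))
    }
})

test_that("windowed similarity is rescaled to [0,1] and tracks identity", {
    same <- ProteinMSA(c(ref = "MKLVNQWE", a = "MKLVNQWE"), "ref")
    expect_true(all(windowedSimilarity(same, 4) == 1))
    sim <- simulateMSA(8, 80,
                       conservedBlocks = data.frame(start = 30, end = 60,
                                                    identity = 0.95),
                       seed = 23L)
    prof <- windowedSimilarity(sim$msa, 20)
    expect_true(all(prof >= 0 & prof <= 1))
    expect_gt(mean(prof[35:55]) - mean(prof[c(1:20, 70:80)]), 0.2)
    bad <- ProteinMSA(c(ref = "AX", s = "AA"), "ref")
    expect_error(windowedSimilarity(bad, 1), "absent from")
})

test_that("Bayes-factor smoothing is a truncated centred average", {
    expect_equal(unname(windowedBayes(
        data.frame(codon = 1:5, bayes_factor = rep(40, 5)), 4)),
        rep(40, 5))
    step <- windowedBayes(
        data.frame(codon = 1:8, bayes_factor = c(0, 0, 0, 0, 80, 80, 80, 80)),
        4)
    expect_equal(unname(step), c(0, 0, 20, 40, 60, 80, 80, 80))
    expect_true(all(diff(step) >= 0))
    x <- windowedBayes(data.frame(codon = c(1, 3, 7),
                                  bayes_factor = c(10, 50, 90)), 4)
    expect_true(all(x >= 10 & x <= 90, na.rm = TRUE))
    expect_error(windowedBayes(data.frame(codon = integer(0),
                                          bayes_factor = numeric(0))),
                 "all codons missing")
})

test_that("proline segmentation partitions the non-proline positions", {
    seg <- prolineSegments("APLLPY")
    expect_equal(IRanges::start(seg), c(1L, 3L, 6L))
    expect_equal(IRanges::end(seg), c(1L, 4L, 6L))
    expect_equal(length(prolineSegments("PP")), 0)
    noP <- prolineSegments("ACDEFG")
    expect_equal(c(IRanges::start(noP), IRanges::end(noP)), c(1L, 6L))
    expect_error(prolineSegments(""), "empty")
    set.seed(24)
    for (trial in 1:10) {
        s <- paste(sample(c("P", "A", "C", "G"), 50, TRUE), collapse = "")
        sg <- prolineSegments(s)
        covered <- unlist(lapply(seq_along(sg), function(i)
            IRanges::start(sg)[i]:IRanges::end(sg)[i]))
        expect_false(any(duplicated(covered)))
        pPos <- which(strsplit(s, "")[[1]] == "P")
        expect_setequal(c(covered, pPos), 1:50)
        expect_false(any(covered %in% pPos))
    }
})

test_that("segment annotation flags selection and conservation correctly", {
    seg <- IRanges::IRanges(start = c(1, 6), end = c(4, 9))
    idp <- c(rep(0.9, 4), NA, rep(0.3, 4))
    bfA <- rep(50, 9); bfB <- rep(39, 9)
    annA <- annotateSegments(seg, idp, bfProfile = bfA,
                             identityThreshold = 0.8)
    expect_equal(S4Vectors::mcols(annA)$selected, c(TRUE, TRUE))
    expect_equal(S4Vectors::mcols(annA)$conserved, c(TRUE, FALSE))
    annB <- annotateSegments(seg, idp, bfProfile = bfB,
                             identityThreshold = 0.8)
    expect_equal(S4Vectors::mcols(annB)$selected, c(FALSE, FALSE))
    expect_error(annotateSegments(IRanges::IRanges(1, 20), idp),
                 "outside profile")
})

test_that("a planted conserved block flags exactly its overlapping
           segments", {
    sim <- simulateMSA(10, 150,
                       conservedBlocks = data.frame(start = 61, end = 100,
                                                    identity = 0.97),
                       prolinePositions = c(20, 40, 60, 101, 120),
                       seed = 25L)
    idp <- windowedIdentity(sim$msa, 4)
    simp <- windowedSimilarity(sim$msa, 20)
    bfp <- windowedBayes(sim$bf, 4)
    segs <- annotateSegments(prolineSegments(sim$msa), idp, simp, bfp,
                             bfCutoff = 40, identityThreshold = 0.8)
    inBlock <- IRanges::start(segs) <= 100 & IRanges::end(segs) >= 61
    expect_equal(S4Vectors::mcols(segs)$selected, inBlock)
    expect_equal(S4Vectors::mcols(segs)$conserved, inBlock)
})
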