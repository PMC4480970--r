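suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (enumeration, brute-force agglomeration) so they
# share no code with the implementation they check.

# Step-up FDR adjustment, written out literally.
bruteForceBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    for (i in seq_len(m)) {
        rank_i <- which(ord == i)
        candidates <- vapply(seq(rank_i, m), function(r) {
            p[ord[r]] * m / r
        }, numeric(1))
        adj[i] <- min(1, min(candidates))
    }
    adj
}

# Complete-linkage agglomeration by direct set bookkeeping; returns the
# sorted merge heights.
bruteForceCompleteLinkHeights <- function(d) {
    d <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(NA, NA)
        bestH <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            h <- max(d[clusters[[i]], clusters[[j]]])
            if (h < bestH) { bestH <- h; best <- c(i, j) }
        }
        heights <- c(heights, bestH)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# Column identity of an alignment matrix by explicit pair enumeration.
pairEnumerationIdentity <- function(mat) {
    apply(mat, 2, function(col) {
        res <- col[col != "-"]
        if (length(res) < 2) return(NA_real_)
        pairs <- utils::combn(length(res), 2)
        mean(res[pairs[1, ]] == res[pairs[2, ]])
    })
}

# A small expressed count experiment with two conditions, two replicates.
makeTinyExperiment <- function(nGenes = 200, seed = 1L, conditions =
                                   c("control", "foxp3"), mu = 100) {
    set.seed(seed)
    cond <- rep(conditions, each = 2)
    k <- matrix(rnbinom(nGenes * length(cond), mu = mu, size = 10),
                nrow = nGenes)
    rownames(k) <- sprintf("g%04d", seq_len(nGenes))
    colnames(k) <- paste0(cond, "_r", rep(1:2, length(conditions)))
    FoxExperiment(k, geneLengths = rep(1000, nGenes), condition = cond)
}
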