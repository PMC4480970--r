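#' Simulate a domain-dissection RNA-seq study with planted ground truth
#'
#' Generates a gene-by-sample count matrix emulating the statistical
#' structure of the emulated study design: a bimodal log2-FPKM landscape
#' over expressed genes, a deterministic fraction of all-zero (NE) genes, a
#' planted set of factor-regulated genes shifted between the control and
#' factor conditions, a reference lineage ("treg") sharing the factor
#' condition's means and naive helper cells sharing the control's, and
#' mutant conditions that revert the planted effect toward the control mean
#' for their dysregulated genes and keep it for the rest.
#'
#' Counts are negative binomial around length- and library-size-scaled
#' means: the true mean count of gene g in sample j is
#' \code{FPKM * length/1e3 * libsize/1e6} (the inverse of the FPKM formula
#' used downstream), with dispersion following the configured mean-dispersion
#' trend. Regulated genes take their expressed-state level from the
#' high-expression mode; upregulated genes sit \code{effect} below that
#' level in control, downregulated genes \code{effect} below it in the
#' factor condition. The same seed always yields bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{experiment} (a \linkS4class{FoxExperiment}) and
#'   \code{truth} (a \linkS4class{GroundTruth}).
#' @export
simulateCounts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    withSeed(config@seed, simulateCountsImpl(config))
}

simulateCountsImpl <- function(config) {
    nG <- config@nGenes
    geneIds <- sprintf("g%05d", seq_len(nG))
    core <- c("naive_th", "treg", "control", "foxp3")
    mutants <- setdiff(config@conditions, core)

    lengths <- round(stats::runif(nG, config@geneLengthRange[1],
                                  config@geneLengthRange[2]))

    nZero <- round(config@fracZero * nG)
    zeroIdx <- sample.int(nG, nZero)
    expressedIdx <- setdiff(seq_len(nG), zeroIdx)

    # expressed-state baseline: bimodal log2 FPKM
    isLE <- stats::runif(length(expressedIdx)) < config@piLE
    base <- numeric(length(expressedIdx))
    base[isLE] <- stats::rnorm(sum(isLE), config@muLE, config@sigmaLE)
    base[!isLE] <- stats::rnorm(sum(!isLE), config@muHE, config@sigmaHE)

    # regulated genes: planted in the high-expression mode so the class
    # filter can see them; effect subtracted on the inactive side
    hePool <- expressedIdx[!isLE]
    if (length(hePool) < config@nRegulated)
        stop("not enough high-mode genes to plant the regulated set")
    regIdx <- sort(sample(hePool, config@nRegulated))
    nUp <- round(config@fracUp * config@nRegulated)
    dirUp <- rep(FALSE, config@nRegulated)
    dirUp[sample.int(config@nRegulated, nUp)] <- TRUE
    effect <- stats::runif(config@nRegulated, config@effectRange[1],
                           config@effectRange[2])

    trueMeans <- matrix(rep(NA_real_, nG * length(config@conditions)),
                        nrow = nG,
                        dimnames = list(geneIds, config@conditions))
    baseAll <- numeric(nG)
    baseAll[expressedIdx] <- base
    for (cc in config@conditions) trueMeans[, cc] <- baseAll
    # active level = the high-mode draw; inactive level = active - effect
    active <- baseAll[regIdx]
    inactive <- active - effect
    ctrlLevel <- ifelse(dirUp, inactive, active)
    foxLevel <- ifelse(dirUp, active, inactive)
    trueMeans[regIdx, "control"] <- ctrlLevel
    trueMeans[regIdx, "naive_th"] <- ctrlLevel
    trueMeans[regIdx, "foxp3"] <- foxLevel
    trueMeans[regIdx, "treg"] <- foxLevel

    dysSets <- list()
    for (m in mutants) {
        spec <- config@mutantDysregulation[[m]]
        trueMeans[regIdx, m] <- foxLevel      # retained by default
        if (is.null(spec)) { dysSets[[m]] <- character(0); next }
        # a single double in [0,1] is a fraction; integer vectors are
        # explicit indices into the regulated set
        if (is.double(spec) && length(spec) == 1 && spec >= 0 &&
            spec <= 1) {
            pick <- sample.int(config@nRegulated,
                               round(spec * config@nRegulated))
        } else {
            pick <- as.integer(spec)
        }
        mult <- config@dysregMultiplier
        trueMeans[regIdx[pick], m] <-
            foxLevel[pick] + mult * (ctrlLevel[pick] - foxLevel[pick])
        dysSets[[m]] <- geneIds[regIdx[sort(pick)]]
    }
    trueMeans[zeroIdx, ] <- -Inf

    # samples
    condVec <- rep(config@conditions, each = config@nReplicates)
    sampleIds <- paste0(condVec, "_r",
                        rep(seq_len(config@nReplicates),
                            times = length(config@conditions)))
    libsize <- stats::runif(length(condVec), config@librarySizeRange[1],
                            config@librarySizeRange[2])

    mu <- 2^trueMeans                                  # linear FPKM
    mu[trueMeans == -Inf] <- 0
    mu <- mu * (lengths / 1e3)                         # per-gene scale
    counts <- matrix(0L, nG, length(condVec),
                     dimnames = list(geneIds, sampleIds))
    meanCount <- rowMeans(mu[, condVec, drop = FALSE]) *
        mean(libsize) / 1e6
    alpha <- pmin(config@dispAlphaMax,
                  config@dispAlpha0 +
                  config@dispAlphaScale / pmax(meanCount, 1e-8))
    for (j in seq_along(condVec)) {
        mj <- mu[, condVec[j]] * libsize[j] / 1e6
        pos <- mj > 0
        counts[pos, j] <- stats::rnbinom(sum(pos), mu = mj[pos],
                                         size = 1 / alpha[pos])
    }

    fe <- FoxExperiment(counts, geneLengths = lengths,
                        condition = condVec)
    colData(fe)$libSize <- libsize
    truth <- new("GroundTruth",
                 regulated = geneIds[regIdx],
                 direction = stats::setNames(
                     c("down", "up")[dirUp + 1L], geneIds[regIdx]),
                 dysregulated = dysSets,
                 trueMeans = trueMeans)
    list(experiment = fe, truth = truth)
}

#' Simulate a protein MSA with planted conserved blocks and a Bayes-factor
#' table
#'
#' Generates an ungapped protein multiple alignment whose realised windowed
#' identity is high inside designated conserved blocks and low outside, a
#' reference sequence carrying prolines at exactly the requested positions
#' (and nowhere else), and a per-codon Bayes-factor table elevated above the
#' selection cutoff inside the blocks.
#'
#' @param nSequences number of sequences (including the reference, named
#'   "ref").
#' @param length alignment length in residues.
#' @param conservedBlocks data.frame with columns \code{start}, \code{end},
#'   \code{identity} (per-position probability that a non-reference
#'   sequence matches the reference inside the block). Overlapping blocks
#'   with conflicting identity levels are a configuration error.
#' @param prolinePositions integer positions of prolines in the reference.
#' @param seed integer seed (bit-identical output for identical seeds).
#' @param backgroundIdentity match probability outside the blocks.
#' @param bfInBlock,bfBackground mean Bayes factor inside/outside blocks;
#'   values are jittered by +-25\% but stay on their side of the usual
#'   cutoff of 40 with the defaults.
#' @return list with \code{msa} (a \linkS4class{ProteinMSA}) and \code{bf}
#'   (data.frame: codon, bayes_factor).
#' @export
simulateMSA <- function(nSequences, length,
                        conservedBlocks = NULL,
                        prolinePositions = integer(0),
                        seed = 1L,
                        backgroundIdentity = 0.4,
                        bfInBlock = 80, bfBackground = 5) {
    if (!is.null(conservedBlocks) && nrow(conservedBlocks)) {
        if (any(conservedBlocks$start < 1) ||
            any(conservedBlocks$end > length) ||
            any(conservedBlocks$start > conservedBlocks$end))
            stop("conserved blocks must lie within [1, length]")
        cov <- rep(NA_real_, length)
        for (i in seq_len(nrow(conservedBlocks))) {
            span <- conservedBlocks$start[i]:conservedBlocks$end[i]
            conflict <- !is.na(cov[span]) &
                cov[span] != conservedBlocks$identity[i]
            if (any(conflict))
                stop("overlapping blocks with conflicting identity levels")
            cov[span] <- conservedBlocks$identity[i]
        }
    }
    withSeed(seed, {
        nonP <- strsplit("ARNDCQEGHILKMFSTWYV", "")[[1]]   # 19 letters, no P
        identity <- rep(backgroundIdentity, length)
        inBlock <- rep(FALSE, length)
        if (!is.null(conservedBlocks) && nrow(conservedBlocks)) {
            for (i in seq_len(nrow(conservedBlocks))) {
                span <- conservedBlocks$start[i]:conservedBlocks$end[i]
                identity[span] <- conservedBlocks$identity[i]
                inBlock[span] <- TRUE
            }
        }
        ref <- sample(nonP, length, replace = TRUE)
        ref[prolinePositions] <- "P"
        seqs <- matrix("", nSequences, length)
        seqs[1, ] <- ref
        for (s in seq_len(nSequences - 1) + 1) {
            keep <- stats::runif(length) < identity
            row <- ref
            sub <- which(!keep)
            for (i in sub)
                row[i] <- sample(setdiff(nonP, ref[i]), 1)
            seqs[s, ] <- row
        }
        ids <- c("ref", sprintf("s%02d", seq_len(nSequences - 1)))
        aln <- Biostrings::AAStringSet(apply(seqs, 1, paste, collapse = ""))
        names(aln) <- ids
        bfMean <- ifelse(inBlock, bfInBlock, bfBackground)
        bf <- data.frame(
            codon = seq_len(length),
            bayes_factor = bfMean * stats::runif(length, 0.75, 1.25))
        list(msa = ProteinMSA(aln, "ref"), bf = bf)
    })
}
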