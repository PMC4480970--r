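#' Run the full regulation-dissection pipeline
#'
#' Binds the stages end to end: expression classification (robust FPKM,
#' bimodal mixture, FDR class boundaries), NB Wald differential expression
#' for the lineage contrast (treg vs naive_th), the factor contrast (foxp3
#' vs control) and every mutant against foxp3, the regulated-set
#' intersection with direction, per-mutant retained/dysregulated calls,
#' direction-split binomial tests against the called regulated baseline,
#' and sample distances / hierarchical clustering / PCA of the regulated
#' genes. Results are written as diff-able TSV/JSON artifacts and returned
#' invisibly.
#'
#' @param config either a \linkS4class{SimulationConfig} (synthetic mode) or
#'   a directory containing \code{counts.tsv}, \code{lengths.tsv} and
#'   \code{meta.tsv} (see [readCountTables()]).
#' @param outDir output directory; NULL skips file output.
#' @param alpha adjusted-p threshold for all differential calls.
#' @param fdrClass FDR level of the expression-class boundaries.
#' @param priorSD shrinkage prior sd for the moderated log2 fold changes.
#' @param mutants mutant condition labels; by default every condition other
#'   than naive_th/treg/control/foxp3. Naming a condition absent from the
#'   metadata is a configuration error.
#' @return (invisibly) a list with the classified experiment, DE results,
#'   regulation table, set summaries, direction-test p-values, distance
#'   matrix, clustering, PCA and (in synthetic mode) the planted truth.
#' @export
runPipeline <- function(config, outDir = NULL, alpha = 0.05,
                        fdrClass = 0.05, priorSD = 2, mutants = NULL) {
    truth <- NULL
    if (is(config, "SimulationConfig")) {
        sim <- simulateCounts(config)
        fox <- sim$experiment
        truth <- sim$truth
        seed <- config@seed
    } else if (is.character(config) && dir.exists(config)) {
        fox <- readCountTables(config)
        seed <- NA_integer_
    } else stop("config must be a SimulationConfig or a data directory")

    cond <- unique(sampleConditions(fox))
    core <- c("naive_th", "treg", "control", "foxp3")
    missingCore <- setdiff(core, cond)
    if (length(missingCore))
        stop("metadata lacks required conditions: ",
             paste(missingCore, collapse = ", "))
    if (is.null(mutants)) mutants <- setdiff(cond, core)
    unknown <- setdiff(mutants, cond)
    if (length(unknown))
        stop("configuration error: unknown mutant condition(s): ",
             paste(unknown, collapse = ", "))

    fox <- computeFPKM(computeSizeFactors(fox))
    fox <- classifyGenes(fox, fdr = fdrClass)
    fox <- estimateDispersions(fox)

    deLineage <- nbWaldTest(fox, "treg", "naive_th", priorSD = priorSD)
    deFactor <- nbWaldTest(fox, "foxp3", "control", priorSD = priorSD)
    deMutants <- lapply(mutants, function(m)
        nbWaldTest(fox, m, "foxp3", priorSD = priorSD))
    names(deMutants) <- mutants

    reg <- callFoxp3Regulated(deLineage, deFactor, fox, alpha = alpha)
    for (m in mutants)
        reg <- callMutantStatus(reg, deMutants[[m]], fox,
                                factorCondition = "foxp3", alpha = alpha)
    sets <- summarizeSets(reg)

    nUp <- sum(reg$direction == "up", na.rm = TRUE)
    nRegTot <- sum(reg$regulated)
    dirTests <- stats::setNames(rep(NA_real_, length(mutants)), mutants)
    for (m in mutants) {
        i <- match(m, sets$perMutant$mutant)
        if (sets$perMutant$dysregulated[i] > 0 && nRegTot > 0)
            dirTests[m] <- directionDistributionTest(
                sets$perMutant$dysUp[i], sets$perMutant$dysDown[i],
                nUp, nRegTot)
    }

    regGenes <- rownames(reg)[reg$regulated]
    expr <- regLog(fox, genes = regGenes)
    dm <- sampleDistances(expr)
    hc <- hierarchicalCluster(dm)
    pca <- if (length(regGenes) >= 2) pcaSummary(expr) else NULL

    summary <- list(
        seed = seed, alpha = alpha, fdrClass = fdrClass, priorSD = priorSD,
        nGenes = nrow(fox),
        regulated = nRegTot, regulatedUp = nUp,
        regulatedDown = nRegTot - nUp,
        perMutant = sets$perMutant,
        directionTestP = as.list(dirTests),
        intersections = sets$intersections,
        pcaVarianceFraction = if (is.null(pca)) NULL
            else pca$varianceFraction)

    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeCountTables(fox, outDir)
        writeTsv(data.frame(gene = rownames(fox),
                            expressionClasses(fox), check.names = FALSE),
                 file.path(outDir, "classes.tsv"),
                 params = list(fdr = fdrClass))
        writeDEResult(deLineage, file.path(outDir, "de_treg_vs_naive.tsv"))
        writeDEResult(deFactor, file.path(outDir, "de_foxp3_vs_control.tsv"))
        for (m in mutants)
            writeDEResult(deMutants[[m]],
                          file.path(outDir,
                                    sprintf("de_%s_vs_foxp3.tsv", m)))
        writeRegulationTable(reg, file.path(outDir, "regulation.tsv"))
        if (!is.null(truth))
            writeGroundTruth(truth, file.path(outDir, "ground_truth.json"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA, na = "null",
                             dataframe = "columns", matrix = "rowmajor")
    }

    invisible(list(experiment = fox, truth = truth,
                   deLineage = deLineage, deFactor = deFactor,
                   deMutants = deMutants, regulation = reg, sets = sets,
                   directionTestP = dirTests, distances = dm,
                   clustering = hc, pca = pca, summary = summary))
}
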