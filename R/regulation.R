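#' Call differential expression with the expression-class filter
#'
#' A gene is differentially expressed for a contrast iff (i) its BH-adjusted
#' Wald p-value is below \code{alpha} and (ii) it is classified INT or HE in
#' at least one sequencing replicate of at least one of the two conditions.
#' Genes classified NE or LE in every replicate of both conditions are
#' ignored as transcriptional noise.
#'
#' @param de a \linkS4class{DEResult} for the contrast.
#' @param object the classified \linkS4class{FoxExperiment} (run through
#'   [classifyGenes()]) providing the NE/LE/INT/HE labels.
#' @param alpha adjusted-p threshold.
#' @return named logical vector over the genes of \code{de}.
#' @export
callDifferential <- function(de, object, alpha = 0.05) {
    stopifnot(is(de, "DEResult"), is(object, "FoxExperiment"))
    cls <- expressionClasses(object)
    if (is.null(cls)) stop("missing class labels: run classifyGenes() first")
    if (!identical(rownames(cls), rownames(de)))
        stop("gene universes of DE result and experiment differ")
    cond <- sampleConditions(object)
    sel <- cond %in% c(metadata(de)$numerator, metadata(de)$denominator)
    hit <- matrix(cls[, sel, drop = FALSE] %in% c("INT", "HE"),
                  nrow = nrow(cls))
    expressed <- rowSums(hit) > 0
    sig <- !is.na(de$padj) & de$padj < alpha
    stats::setNames(sig & expressed, rownames(de))
}

#' Call factor-regulated, lineage-relevant genes
#'
#' The regulated set is the intersection of the genes differentially
#' expressed in the lineage-defining contrast (reference lineage vs naive
#' helper cells) and in the factor-transduction contrast (factor vs control
#' vector), each filtered by the expression classes ([callDifferential()]).
#' The direction of regulation is the sign of the factor-vs-control log2
#' fold change.
#'
#' @param deLineage \linkS4class{DEResult} for reference lineage vs naive
#'   cells (e.g. treg vs naive_th).
#' @param deFactor \linkS4class{DEResult} for factor vs control (e.g. foxp3
#'   vs control); its orientation is read from \code{metadata()}.
#' @param object the classified \linkS4class{FoxExperiment}.
#' @param alpha adjusted-p threshold.
#' @return a \linkS4class{RegulationTable} with columns \code{regulated} and
#'   \code{direction}.
#' @export
callFoxp3Regulated <- function(deLineage, deFactor, object, alpha = 0.05) {
    if (!identical(rownames(deLineage), rownames(deFactor)))
        stop("gene universes of the two DE results differ")
    d1 <- callDifferential(deLineage, object, alpha)
    d2 <- callDifferential(deFactor, object, alpha)
    regulated <- d1 & d2
    direction <- rep(NA_character_, length(regulated))
    direction[regulated] <- ifelse(deFactor$log2fc[regulated] > 0,
                                   "up", "down")
    out <- DataFrame(regulated = regulated, direction = direction,
                     row.names = rownames(deFactor))
    res <- new("RegulationTable", out)
    metadata(res) <- list(alpha = alpha, mutants = character(0))
    res
}

#' Score a mutant condition: retained vs dysregulated
#'
#' A regulated gene is dysregulated in a mutant iff it is differentially
#' expressed between the factor condition and the mutant (adjusted p below
#' \code{alpha}, expression-class filter applied) AND its change relative to
#' the factor condition points in the direction of the control condition,
#' i.e. opposite to the factor's own effect. Significant changes in the
#' opposite direction (enhanced upregulation of factor-induced genes, or
#' deeper downregulation of factor-suppressed genes) count as retaining
#' factor control, as does no significant change. Non-regulated genes are
#' untested.
#'
#' @param regulation a \linkS4class{RegulationTable} from
#'   [callFoxp3Regulated()].
#' @param deMutant \linkS4class{DEResult} contrasting the mutant with the
#'   factor condition (either orientation; resolved from metadata, the
#'   factor condition must be one side).
#' @param object the classified \linkS4class{FoxExperiment}.
#' @param factorCondition label of the wild-type factor condition.
#' @param alpha adjusted-p threshold.
#' @return the regulation table with a \code{status_<mutant>} column added.
#' @export
callMutantStatus <- function(regulation, deMutant, object,
                             factorCondition = "foxp3", alpha = 0.05) {
    stopifnot(is(regulation, "RegulationTable"), is(deMutant, "DEResult"))
    if (!identical(rownames(regulation), rownames(deMutant)))
        stop("gene universes differ")
    md <- metadata(deMutant)
    if (md$numerator == factorCondition) {
        mutant <- md$denominator
        lfcMutVsFactor <- -deMutant$log2fc
    } else if (md$denominator == factorCondition) {
        mutant <- md$numerator
        lfcMutVsFactor <- deMutant$log2fc
    } else stop("deMutant does not contrast against ", factorCondition)

    diffExpr <- callDifferential(deMutant, object, alpha)
    # direction of control relative to the factor condition is the reverse
    # of the factor's own effect
    towardControl <- ifelse(regulation$direction == "up",
                            lfcMutVsFactor < 0, lfcMutVsFactor > 0)
    status <- rep("untested", nrow(regulation))
    reg <- regulation$regulated
    status[reg] <- ifelse(diffExpr[reg] & towardControl[reg],
                          "dysregulated", "retained")
    regulation[[paste0("status_", mutant)]] <- status
    metadata(regulation)$mutants <- c(metadata(regulation)$mutants, mutant)
    regulation
}

#' Summarise regulation calls across mutants
#'
#' Emits per-mutant dysregulated/retained counts split by the direction of
#' factor regulation (the layout of the direction-split table) and the
#' pairwise intersection sizes of the dysregulated sets for Venn-style
#' output.
#'
#' @param regulation a \linkS4class{RegulationTable} with one or more
#'   \code{status_} columns.
#' @return a list with \code{perMutant} (data.frame: mutant, dysregulated,
#'   retained, dysUp, dysDown), \code{dysregulatedSets} (named list of gene
#'   identifiers) and \code{intersections} (symmetric matrix of pairwise
#'   intersection sizes).
#' @export
summarizeSets <- function(regulation) {
    stopifnot(is(regulation, "RegulationTable"))
    mutants <- metadata(regulation)$mutants
    genes <- rownames(regulation)
    sets <- list()
    per <- data.frame(mutant = mutants, dysregulated = 0L, retained = 0L,
                      dysUp = 0L, dysDown = 0L)
    for (i in seq_along(mutants)) {
        st <- regulation[[paste0("status_", mutants[i])]]
        dys <- st == "dysregulated"
        sets[[mutants[i]]] <- genes[dys]
        per$dysregulated[i] <- sum(dys)
        per$retained[i] <- sum(st == "retained")
        per$dysUp[i] <- sum(dys & regulation$direction == "up",
                            na.rm = TRUE)
        per$dysDown[i] <- sum(dys & regulation$direction == "down",
                              na.rm = TRUE)
    }
    inter <- matrix(0L, length(mutants), length(mutants),
                    dimnames = list(mutants, mutants))
    for (i in seq_along(mutants)) for (j in seq_along(mutants))
        inter[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    list(perMutant = per, dysregulatedSets = sets, intersections = inter)
}
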