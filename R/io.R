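# Tabular readers/writers. All outputs are TSV with a header line preceded
# by '#'-prefixed comment metadata; readers skip comment lines, so every
# writer round-trips through its own reader.

tsvHeader <- function(con, params = list()) {
    writeLines(sprintf("# TregDissect %s",
                       as.character(utils::packageVersion("TregDissect"))),
               con)
    for (nm in names(params))
        writeLines(sprintf("# %s: %s", nm,
                           paste(params[[nm]], collapse = ",")), con)
}

writeTsv <- function(df, file, params = list()) {
    con <- file(file, "w")
    on.exit(close(con))
    tsvHeader(con, params)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

readTsv <- function(file, ...) {
    utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, ...)
}

#' Write / read a count experiment as plain TSV tables
#'
#' \code{writeCountTables} writes three files into \code{dir}:
#' \code{counts.tsv} (first column \code{gene}, one column per sample),
#' \code{lengths.tsv} (gene, length) and \code{meta.tsv} (sample, condition,
#' replicate). \code{readCountTables} reconstructs the
#' \linkS4class{FoxExperiment}.
#'
#' @param object a \linkS4class{FoxExperiment}.
#' @param dir output directory (created if absent).
#' @return \code{writeCountTables}: the directory, invisibly;
#'   \code{readCountTables}: a \linkS4class{FoxExperiment}.
#' @export
writeCountTables <- function(object, dir) {
    stopifnot(is(object, "FoxExperiment"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(data.frame(gene = rownames(object), counts(object),
                        check.names = FALSE),
             file.path(dir, "counts.tsv"))
    writeTsv(data.frame(gene = rownames(object),
                        length = unname(geneLengths(object))),
             file.path(dir, "lengths.tsv"))
    writeTsv(data.frame(sample = colnames(object),
                        condition = colData(object)$condition,
                        replicate = colData(object)$replicate),
             file.path(dir, "meta.tsv"))
    invisible(dir)
}

#' @rdname writeCountTables
#' @export
readCountTables <- function(dir) {
    k <- readTsv(file.path(dir, "counts.tsv"))
    lens <- readTsv(file.path(dir, "lengths.tsv"))
    meta <- readTsv(file.path(dir, "meta.tsv"))
    counts <- as.matrix(k[, -1, drop = FALSE])
    rownames(counts) <- k$gene
    FoxExperiment(counts,
                  geneLengths = stats::setNames(lens$length, lens$gene),
                  condition = meta$condition[match(colnames(counts),
                                                   meta$sample)],
                  replicate = meta$replicate[match(colnames(counts),
                                                   meta$sample)])
}

#' Write / read planted ground truth as JSON
#' @param truth a \linkS4class{GroundTruth}.
#' @param file path of the JSON file.
#' @return \code{readGroundTruth}: a \linkS4class{GroundTruth} (without the
#'   true-mean matrix, which is written alongside as TSV only when
#'   \code{meansFile} is given).
#' @param meansFile optional TSV path for the true mean matrix.
#' @export
writeGroundTruth <- function(truth, file, meansFile = NULL) {
    stopifnot(is(truth, "GroundTruth"))
    jsonlite::write_json(
        list(regulated = truth@regulated,
             direction = as.list(truth@direction),
             dysregulated = truth@dysregulated),
        file, auto_unbox = TRUE, digits = NA)
    if (!is.null(meansFile))
        writeTsv(data.frame(gene = rownames(truth@trueMeans),
                            truth@trueMeans, check.names = FALSE),
                 meansFile)
    invisible(file)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(file) {
    x <- jsonlite::read_json(file, simplifyVector = TRUE)
    new("GroundTruth",
        regulated = x$regulated,
        direction = unlist(x$direction)[x$regulated],
        dysregulated = lapply(x$dysregulated, as.character),
        trueMeans = matrix(numeric(0), 0, 0))
}

#' Write a DE result as TSV
#' @param de a \linkS4class{DEResult}.
#' @param file output path.
#' @export
writeDEResult <- function(de, file) {
    stopifnot(is(de, "DEResult"))
    writeTsv(data.frame(gene = rownames(de), as.data.frame(de),
                        check.names = FALSE),
             file, params = metadata(de)[c("numerator", "denominator",
                                           "priorSD")])
    invisible(file)
}

#' Write a regulation table as TSV
#' @param regulation a \linkS4class{RegulationTable}.
#' @param file output path.
#' @export
writeRegulationTable <- function(regulation, file) {
    stopifnot(is(regulation, "RegulationTable"))
    writeTsv(data.frame(gene = rownames(regulation),
                        as.data.frame(regulation), check.names = FALSE),
             file,
             params = list(alpha = metadata(regulation)$alpha,
                           mutants = metadata(regulation)$mutants))
    invisible(file)
}

#' Read an aligned protein FASTA as a ProteinMSA
#' @param file aligned FASTA path.
#' @param refId name of the reference sequence.
#' @return a \linkS4class{ProteinMSA}.
#' @export
readProteinMSA <- function(file, refId) {
    ProteinMSA(Biostrings::readAAStringSet(file), refId)
}

#' Write a ProteinMSA as aligned FASTA
#' @param msa a \linkS4class{ProteinMSA}.
#' @param file output path.
#' @export
writeProteinMSA <- function(msa, file) {
    Biostrings::writeXStringSet(msa@aln, file)
    invisible(file)
}

#' Read / write a per-codon Bayes-factor table (TSV: codon, bayes_factor)
#' @param file TSV path.
#' @return \code{readBayesFactors}: data.frame with columns \code{codon}
#'   and \code{bayes_factor}.
#' @export
readBayesFactors <- function(file) {
    bf <- readTsv(file)
    if (!all(c("codon", "bayes_factor") %in% names(bf)))
        stop("expected columns 'codon' and 'bayes_factor'")
    bf
}

#' @rdname readBayesFactors
#' @param bf data.frame with columns \code{codon} and \code{bayes_factor}.
#' @export
writeBayesFactors <- function(bf, file) {
    writeTsv(bf[, c("codon", "bayes_factor")], file)
    invisible(file)
}

#' Write conservation profiles and annotated segments
#'
#' Profiles go to a TSV with columns position, identity, similarity, bf;
#' segments to a BED-like TSV (reference name, 0-based half-open start, end,
#' flags) and, mirrored, to JSON.
#'
#' @param identity,similarity,bf profiles over reference positions (either
#'   may be NULL).
#' @param segments annotated \linkS4class{IRanges} from
#'   [annotateSegments()].
#' @param profileFile,segmentFile,segmentJson output paths (NULL to skip).
#' @param refName reference name used in the BED-like output.
#' @export
writeConservationScan <- function(identity, similarity = NULL, bf = NULL,
                                  segments = NULL,
                                  profileFile = NULL, segmentFile = NULL,
                                  segmentJson = NULL, refName = "ref") {
    L <- length(identity)
    pad <- function(x) if (is.null(x)) rep(NA_real_, L)
        else c(x, rep(NA_real_, max(0, L - length(x))))[seq_len(L)]
    if (!is.null(profileFile))
        writeTsv(data.frame(position = seq_len(L),
                            identity = as.numeric(identity),
                            similarity = pad(similarity),
                            bf = pad(bf)),
                 profileFile)
    if (!is.null(segments)) {
        segDf <- data.frame(ref = refName,
                            start = start(segments) - 1L,
                            end = end(segments),
                            as.data.frame(mcols(segments)))
        if (!is.null(segmentFile)) writeTsv(segDf, segmentFile)
        if (!is.null(segmentJson))
            jsonlite::write_json(segDf, segmentJson, auto_unbox = TRUE,
                                 digits = NA, na = "null")
    }
    invisible(NULL)
}
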