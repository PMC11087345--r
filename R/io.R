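#' Read a delimited expression matrix
#'
#' Loads a genes x samples table (first column gene ids, header row sample
#' ids).  Duplicate gene ids are collapsed by their mean (with a message);
#' rows that are entirely missing are dropped; any remaining missing cell is
#' an error.  Column (sample) order is preserved exactly as in the file.
#'
#' @param path path to a TSV/CSV file.
#' @param scaleHint declared scale of the values, \code{"linear"} or
#'   \code{"log2"}; linear values must be non-negative.
#' @param sep field separator (default tab).
#' @return A \linkS4class{StageExperiment} without design metadata; attach
#'   the design with \code{\link{StageExperiment}} or
#'   \code{\link{readStageExperiment}}.
#' @export
readExpressionMatrix <- function(path, scaleHint = c("log2", "linear"),
                                 sep = "\t") {
    scaleHint <- match.arg(scaleHint)
    header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
    if (length(header) < 2L)
        stop("malformed header in ", path, ": need gene id column + samples")
    sampleIds <- header[-1]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample id in header: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = c("character",
                                            rep("numeric", length(sampleIds))),
                             check.names = FALSE, quote = "",
                             comment.char = "")
    ids <- tab[[1]]
    m <- as.matrix(tab[, -1, drop = FALSE])
    allMissing <- rowSums(!is.na(m)) == 0L
    if (any(allMissing)) {
        message("dropping ", sum(allMissing), " all-missing row(s)")
        m <- m[!allMissing, , drop = FALSE]
        ids <- ids[!allMissing]
    }
    if (anyDuplicated(ids)) {
        dup <- unique(ids[duplicated(ids)])
        message("collapsing ", length(dup),
                " duplicated gene id(s) by mean")
        m <- rowsum(m, group = ids, reorder = FALSE) /
            as.vector(table(factor(ids, levels = unique(ids))))
        ids <- rownames(m)
    }
    if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop("missing value at gene ", ids[bad[1]], ", sample ",
             sampleIds[bad[2]])
    }
    if (identical(scaleHint, "linear") && any(m < 0)) {
        bad <- which(m < 0, arr.ind = TRUE)[1, ]
        stop("negative value at gene ", ids[bad[1]], ", sample ",
             sampleIds[bad[2]], " with scaleHint = \"linear\"")
    }
    rownames(m) <- ids
    colnames(m) <- sampleIds
    StageExperiment(m, exprScale = scaleHint)
}

#' Read sample metadata
#'
#' @param path TSV with columns \code{sample_id}, \code{group}
#'   (control/case), \code{time_h}, \code{replicate}.
#' @return data.frame of the design, one row per sample.
#' @export
readSampleInfo <- function(path) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "")
    req <- c("sample_id", "group", "time_h", "replicate")
    miss <- setdiff(req, colnames(tab))
    if (length(miss))
        stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$sample_id))
        stop("duplicate sample_id in metadata")
    if (!all(tab$group %in% c("control", "case")))
        stop("group must be \"control\" or \"case\"")
    tab
}

#' Read expression and design together
#'
#' @inheritParams readExpressionMatrix
#' @param infoPath path to the sample-metadata TSV
#'   (see \code{\link{readSampleInfo}}).
#' @return a \linkS4class{StageExperiment} with design attached.
#' @export
readStageExperiment <- function(path, infoPath,
                                scaleHint = c("log2", "linear")) {
    se <- readExpressionMatrix(path, scaleHint = scaleHint)
    info <- readSampleInfo(infoPath)
    StageExperiment(assay(se, "exprs"), sampleInfo = info,
                    exprScale = exprScale(se))
}

#' Read a GMT gene-set collection
#'
#' Standard Broad-dialect GMT: one set per line, fields
#' \code{name TAB description TAB member TAB member ...}.  Members are
#' deduplicated preserving first occurrence; duplicated set names are an
#' error.
#'
#' @param path path to a GMT file.
#' @return A \linkS4class{GeneSetList}; an empty file yields an empty
#'   collection.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(GeneSetList())
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3L))
        stop("GMT parse error at line ", which(nf < 3L)[1],
             ": fewer than 3 fields")
    nm <- vapply(parts, `[[`, "", 1L)
    if (anyDuplicated(nm))
        stop("duplicate gene set name: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(parts, `[[`, "", 2L)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- nm
    GeneSetList(sets, descriptions = desc)
}

#' Write a gene-set collection as GMT
#'
#' @param gsl a \linkS4class{GeneSetList}.
#' @param path output path.
#' @export
writeGmt <- function(gsl, path) {
    lines <- vapply(names(gsl), function(nm) {
        paste(c(nm, gsl@descriptions[[nm]], gsl[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Write a result table as TSV
#'
#' Writes any data.frame-like result with full float precision (values
#' survive a read/write round trip to 1e-12 or better) and without quoting.
#' Row order is the order of \code{x}; result-producing functions in this
#' package document their sort key.
#'
#' @param x data.frame or \code{DataFrame} with named columns.
#' @param path output path.
#' @export
writeResultTable <- function(x, path) {
    x <- as.data.frame(x)
    ok <- tryCatch({
        utils::write.table(format(x, digits = 17, trim = TRUE,
                                  scientific = NA),
                           path, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = TRUE)
        TRUE
    }, error = function(e) stop("cannot write ", path, ": ",
                                conditionMessage(e)))
    invisible(path)
}

#' Read back a result table written by \code{writeResultTable}
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "",
                      comment.char = "")
}

#' Write an expression matrix (with scale) as TSV
#'
#' First column \code{gene_id}, then one column per sample.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(se, path) {
    m <- assay(se, "exprs")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    writeResultTable(df, path)
}
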