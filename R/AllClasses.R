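#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData colData<-
NULL

#' StageExperiment: a two-group time-course expression container
#'
#' Extends \linkS4class{SummarizedExperiment} with an explicit expression
#' scale (\code{"linear"} or \code{"log2"}).  The single assay \code{"exprs"}
#' holds a genes x samples matrix; \code{colData} optionally carries the
#' time-course design in the columns \code{group} (\code{"control"} /
#' \code{"case"}), \code{time_h} (hours post induction) and
#' \code{replicate}.
#'
#' @slot exprScale character, \code{"linear"} or \code{"log2"}.
#' @export
setClass("StageExperiment",
    contains = "SummarizedExperiment",
    slots = c(exprScale = "character"))

setValidity("StageExperiment", function(object) {
    msg <- character()
    if (length(object@exprScale) != 1L ||
        !object@exprScale %in% c("linear", "log2"))
        msg <- c(msg, "exprScale must be \"linear\" or \"log2\"")
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay \"exprs\" is required")
    else {
        x <- SummarizedExperiment::assay(object, "exprs")
        if (anyNA(x))
            msg <- c(msg, "expression matrix contains missing values")
        else if (identical(object@exprScale, "linear") && any(x < 0))
            msg <- c(msg, "linear-scale expression must be non-negative")
        if (anyDuplicated(rownames(x)))
            msg <- c(msg, "gene ids must be unique")
        if (anyDuplicated(colnames(x)))
            msg <- c(msg, "sample ids must be unique")
    }
    cd <- colData(object)
    if ("group" %in% colnames(cd) &&
        !all(cd$group %in% c("control", "case")))
        msg <- c(msg, "group must be \"control\" or \"case\"")
    if ("time_h" %in% colnames(cd) &&
        (!is.numeric(cd$time_h) || any(cd$time_h <= 0)))
        msg <- c(msg, "time_h must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a StageExperiment
#'
#' @param exprs numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames).
#' @param sampleInfo optional \code{data.frame}/\code{DataFrame} with columns
#'   \code{sample_id}, \code{group}, \code{time_h}, \code{replicate};
#'   matched to \code{colnames(exprs)} (every sample must have exactly one
#'   row).
#' @param exprScale scale of \code{exprs}: \code{"linear"} (non-negative) or
#'   \code{"log2"}.
#'
#' @return A \linkS4class{StageExperiment}.
#' @examples
#' m <- matrix(rnorm(12, 6), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' StageExperiment(m, exprScale = "log2")
#' @export
StageExperiment <- function(exprs, sampleInfo = NULL,
                            exprScale = c("log2", "linear")) {
    exprScale <- match.arg(exprScale)
    exprs <- as.matrix(exprs)
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("expression matrix needs gene rownames and sample colnames")
    cd <- DataFrame(row.names = colnames(exprs))
    if (!is.null(sampleInfo)) {
        sampleInfo <- as.data.frame(sampleInfo)
        req <- c("sample_id", "group", "time_h", "replicate")
        miss <- setdiff(req, colnames(sampleInfo))
        if (length(miss))
            stop("sampleInfo lacks column(s): ", paste(miss, collapse = ", "))
        if (anyDuplicated(sampleInfo$sample_id))
            stop("duplicate sample_id in sampleInfo")
        idx <- match(colnames(exprs), sampleInfo$sample_id)
        if (anyNA(idx))
            stop("samples without metadata: ",
                 paste(colnames(exprs)[is.na(idx)], collapse = ", "))
        cd <- DataFrame(group = as.character(sampleInfo$group[idx]),
                        time_h = as.numeric(sampleInfo$time_h[idx]),
                        replicate = as.integer(sampleInfo$replicate[idx]),
                        row.names = colnames(exprs))
    }
    se <- SummarizedExperiment(assays = list(exprs = exprs), colData = cd)
    new("StageExperiment", se, exprScale = exprScale)
}

#' Gene set collection
#'
#' Named list of deduplicated gene-id vectors with one description per set,
#' as read from a GMT file.
#'
#' @slot sets named list of character vectors (unique names, each non-empty,
#'   members deduplicated).
#' @slot descriptions named character vector parallel to \code{sets}.
#' @export
setClass("GeneSetList",
    slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetList", function(object) {
    msg <- character()
    if (length(object@sets)) {
        if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
            msg <- c(msg, "set names must be unique and non-empty")
        if (any(lengths(object@sets) == 0L))
            msg <- c(msg, "every set must be non-empty")
        if (any(vapply(object@sets, anyDuplicated, 0L) > 0L))
            msg <- c(msg, "set members must be deduplicated")
    }
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per set required")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of gene ids; duplicates
#'   within a set are removed keeping first occurrence.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A \linkS4class{GeneSetList}.
#' @export
GeneSetList <- function(sets = list(), descriptions = NULL) {
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    else
        names(descriptions) <- names(sets)
    new("GeneSetList", sets = sets, descriptions = descriptions)
}

#' Per-stage representative expression profile
#'
#' Genes x stages matrix of linear-scale representative expression, the
#' substrate of the Tau specificity index.  Stages are the case time points
#' of the design, in hours.
#'
#' @slot values non-negative numeric matrix, genes x stages.
#' @slot stages numeric vector of stage time points (hours), ordered.
#' @slot flooredGenes character, gene ids whose profile was floored at the
#'   zero-safety epsilon.
#' @export
setClass("StageProfile",
    slots = c(values = "matrix", stages = "numeric",
              flooredGenes = "character"))

setValidity("StageProfile", function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@stages))
        msg <- c(msg, "one column per stage required")
    if (length(object@stages) < 2L)
        msg <- c(msg, "at least 2 stages required")
    if (is.unsorted(object@stages, strictly = TRUE))
        msg <- c(msg, "stages must be strictly increasing")
    if (any(object@values < 0))
        msg <- c(msg, "profile values must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Single-gene-set enrichment trajectory over a time course
#'
#' Per-sample ssGSEA scores for one gene set, summarized per time point as
#' the mean score over case samples; \code{peakTime} is the time point
#' maximizing the per-time score (earliest on ties).
#'
#' @slot geneSetName character.
#' @slot sampleScores named numeric, one ssGSEA score per sample.
#' @slot timeScores numeric named by time point (hours): mean case score.
#' @slot peakTime numeric scalar.
#' @export
setClass("EnrichmentTrajectory",
    slots = c(geneSetName = "character", sampleScores = "numeric",
              timeScores = "numeric", peakTime = "numeric"))

setValidity("EnrichmentTrajectory", function(object) {
    msg <- character()
    tp <- as.numeric(names(object@timeScores))
    if (anyNA(tp)) msg <- c(msg, "timeScores must be named by time points")
    else if (!object@peakTime %in% tp)
        msg <- c(msg, "peakTime must be one of the time points")
    if (length(msg)) msg else TRUE
})

#' Progression/remission partition of a time course
#'
#' Splits the design time points at the peak of an enrichment trajectory:
#' progression = time points at or before the peak, remission = after.
#'
#' @slot peakTime numeric scalar (hours).
#' @slot progression numeric, time points <= peak.
#' @slot remission numeric, time points > peak (possibly empty).
#' @export
setClass("StagePartition",
    slots = c(peakTime = "numeric", progression = "numeric",
              remission = "numeric"))

setValidity("StagePartition", function(object) {
    msg <- character()
    if (!object@peakTime %in% object@progression)
        msg <- c(msg, "peak must belong to the progression stages")
    if (length(intersect(object@progression, object@remission)))
        msg <- c(msg, "progression and remission must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Per-sample cell-type abundance scores
#'
#' Samples x cell types grid produced either by marker-set ssGSEA scoring
#' (\code{mode = "marker_ssgsea"}, arbitrary score scale) or by non-negative
#' least-squares deconvolution (\code{mode = "deconvolution"}, rows are
#' proportions summing to 1; \code{residuals} holds the per-sample residual
#' norm).
#'
#' @slot scores numeric matrix, samples x cell types.
#' @slot mode character, \code{"marker_ssgsea"} or \code{"deconvolution"}.
#' @slot residuals numeric, per-sample residual norms (deconvolution only).
#' @export
setClass("CellTypeScores",
    slots = c(scores = "matrix", mode = "character", residuals = "numeric"))

setValidity("CellTypeScores", function(object) {
    msg <- character()
    if (!object@mode %in% c("marker_ssgsea", "deconvolution"))
        msg <- c(msg, "mode must be marker_ssgsea or deconvolution")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (identical(object@mode, "deconvolution")) {
        if (any(object@scores < -1e-9))
            msg <- c(msg, "proportions must be non-negative")
        if (any(abs(rowSums(object@scores) - 1) > 1e-9))
            msg <- c(msg, "proportion rows must sum to 1")
    }
    if (length(msg)) msg else TRUE
})
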