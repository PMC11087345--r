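#' @rdname StageExperiment-class
#' @aliases exprScale,StageExperiment-method
#' @param object a \linkS4class{StageExperiment}
#' @export
setMethod("exprScale", "StageExperiment", function(object) object@exprScale)

#' @rdname StageExperiment-class
#' @export
setMethod("linearExprs", "StageExperiment", function(object) {
    x <- assay(object, "exprs")
    if (identical(object@exprScale, "log2")) 2^x else x
})

#' Time points of the design, sorted
#' @param object a \linkS4class{StageExperiment} with design metadata
#' @return numeric vector of distinct time points in hours
#' @export
timePoints <- function(object) {
    cd <- colData(object)
    if (!"time_h" %in% colnames(cd))
        stop("no time-course design attached (colData lacks time_h)")
    sort(unique(as.numeric(cd$time_h)))
}

.requireDesign <- function(object) {
    cd <- colData(object)
    need <- c("group", "time_h")
    if (!all(need %in% colnames(cd)))
        stop("StageExperiment has no group/time design attached")
    invisible(cd)
}

setMethod("show", "StageExperiment", function(object) {
    cat("StageExperiment:", nrow(object), "genes x", ncol(object),
        "samples (", object@exprScale, "scale )\n")
    cd <- colData(object)
    if (all(c("group", "time_h") %in% colnames(cd))) {
        cat("  time points (h):",
            paste(sort(unique(cd$time_h)), collapse = ", "), "\n")
        cat("  groups:", paste(sprintf("%s=%d", names(table(cd$group)),
            table(cd$group)), collapse = ", "), "\n")
    }
})

#' @rdname GeneSetList-class
#' @export
setMethod("geneSets", "GeneSetList", function(object) object@sets)

#' @rdname GeneSetList-class
#' @param x,i a \linkS4class{GeneSetList} and a set name or index
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @rdname GeneSetList-class
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @rdname GeneSetList-class
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

setMethod("show", "GeneSetList", function(object) {
    cat("GeneSetList with", length(object@sets), "set(s)\n")
    if (length(object@sets)) {
        n <- head(names(object@sets), 5)
        for (s in n)
            cat(sprintf("  %s (%d genes)\n", s, length(object@sets[[s]])))
        if (length(object@sets) > 5) cat("  ...\n")
    }
})

#' @rdname StageProfile-class
#' @export
setMethod("stages", "StageProfile", function(object) object@stages)

#' @rdname StageProfile-class
#' @export
setMethod("stageValues", "StageProfile", function(object) object@values)

setMethod("show", "StageProfile", function(object) {
    cat("StageProfile:", nrow(object@values), "genes x",
        length(object@stages), "stages (",
        paste(object@stages, collapse = ", "), "h )\n")
    if (length(object@flooredGenes))
        cat("  floored genes:", length(object@flooredGenes), "\n")
})

#' @rdname EnrichmentTrajectory-class
#' @param object an \linkS4class{EnrichmentTrajectory}
#' @export
setMethod("sampleScores", "EnrichmentTrajectory",
          function(object) object@sampleScores)

#' @rdname EnrichmentTrajectory-class
#' @export
setMethod("timeScores", "EnrichmentTrajectory",
          function(object) object@timeScores)

#' @rdname EnrichmentTrajectory-class
#' @export
setMethod("peakTime", "EnrichmentTrajectory",
          function(object) object@peakTime)

setMethod("show", "EnrichmentTrajectory", function(object) {
    cat("EnrichmentTrajectory for", object@geneSetName, "\n")
    print(round(object@timeScores, 4))
    cat("  peak at", object@peakTime, "h\n")
})

#' @rdname StagePartition-class
#' @param object a \linkS4class{StagePartition}
#' @export
setMethod("peakTime", "StagePartition", function(object) object@peakTime)

#' @rdname StagePartition-class
#' @export
setMethod("progressionStages", "StagePartition",
          function(object) object@progression)

#' @rdname StagePartition-class
#' @export
setMethod("remissionStages", "StagePartition",
          function(object) object@remission)

setMethod("show", "StagePartition", function(object) {
    cat("StagePartition: peak", object@peakTime, "h\n")
    cat("  progression:", paste(object@progression, collapse = ", "), "h\n")
    cat("  remission:",
        if (length(object@remission))
            paste(object@remission, collapse = ", ") else "(none)", "h\n")
})

#' @rdname CellTypeScores-class
#' @param object a \linkS4class{CellTypeScores}
#' @export
setMethod("cellTypeScores", "CellTypeScores", function(object) object@scores)

#' @rdname CellTypeScores-class
#' @export
setMethod("scoreMode", "CellTypeScores", function(object) object@mode)

setMethod("show", "CellTypeScores", function(object) {
    cat("CellTypeScores (", object@mode, "):", nrow(object@scores),
        "samples x", ncol(object@scores), "cell types\n")
})
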