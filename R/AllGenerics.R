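#' @describeIn StageExperiment scale of the stored expression values
#' @param object a package object
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))

#' @describeIn StageExperiment the expression matrix on the linear scale
#'   (back-transformed with \code{2^x} when stored as log2)
#' @export
setGeneric("linearExprs", function(object) standardGeneric("linearExprs"))

#' @rdname GeneSetList-class
#' @param object a \linkS4class{GeneSetList}
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname StageProfile-class
#' @param object a package object with stages
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))

#' @rdname StageProfile-class
#' @export
setGeneric("stageValues", function(object) standardGeneric("stageValues"))

#' @rdname EnrichmentTrajectory-class
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))

#' @rdname EnrichmentTrajectory-class
#' @export
setGeneric("timeScores", function(object) standardGeneric("timeScores"))

#' @rdname EnrichmentTrajectory-class
#' @export
setGeneric("peakTime", function(object) standardGeneric("peakTime"))

#' @rdname StagePartition-class
#' @export
setGeneric("progressionStages",
           function(object) standardGeneric("progressionStages"))

#' @rdname StagePartition-class
#' @export
setGeneric("remissionStages",
           function(object) standardGeneric("remissionStages"))

#' @rdname CellTypeScores-class
#' @export
setGeneric("cellTypeScores",
           function(object) standardGeneric("cellTypeScores"))

#' @rdname CellTypeScores-class
#' @export
setGeneric("scoreMode", function(object) standardGeneric("scoreMode"))
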