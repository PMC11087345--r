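#' Configuration for the synthetic time-course generator
#'
#' Describes a two-group (control vs case) time-course design with planted
#' ground truth: stage-specifically high/low genes, a pathway whose
#' activation follows a unimodal trajectory peaking at one time point, and
#' an immune signature whose activation rises from an onset time point
#' onward.  Defaults emulate a kainic-acid-style rodent time course: five
#' time points (1, 6, 24, 72, 240 h), three replicates per group per time
#' point, log2-normal baselines.
#'
#' @param nGenes total number of genes.
#' @param timePointsH ordered positive time points (hours).
#' @param replicates replicates per group per time point.
#' @param baselineLog2Mean,baselineLog2Sd per-gene baseline distribution on
#'   the log2 scale.
#' @param noiseLog2Sd replicate noise sd (log2).
#' @param nSpecificPerStage number of stage-specific genes planted per stage
#'   and per direction (that many "up" and that many "down" at each stage).
#' @param specificLog2Fc planted log2 fold change of stage-specific genes at
#'   their stage (case samples only).
#' @param pathwaySize number of pathway genes sharing the planted unimodal
#'   trajectory.
#' @param pathwayPeakTimeH time point at which the pathway activation peaks;
#'   must be one of \code{timePointsH}.
#' @param pathwayAmplitudeLog2 peak activation (log2 shift in case samples).
#' @param nImmune number of immune-signature genes; their activation is 0
#'   before \code{immuneOnsetTimeH} and rises linearly in log-time from
#'   \code{immuneAmplitudeLog2/2} at onset to \code{immuneAmplitudeLog2} at
#'   the final time point.
#' @param immuneOnsetTimeH onset of the immune activation.
#' @param immuneAmplitudeLog2 immune activation at the final time point.
#' @param seed integer seed; the generator is deterministic given the
#'   configuration.
#' @return a validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nGenes = 2000,
                            timePointsH = c(1, 6, 24, 72, 240),
                            replicates = 3,
                            baselineLog2Mean = 6,
                            baselineLog2Sd = 1.5,
                            noiseLog2Sd = 0.3,
                            nSpecificPerStage = 10,
                            specificLog2Fc = 3,
                            pathwaySize = 50,
                            pathwayPeakTimeH = 24,
                            pathwayAmplitudeLog2 = 1.5,
                            nImmune = 0,
                            immuneOnsetTimeH = 24,
                            immuneAmplitudeLog2 = 2,
                            seed = 1) {
    cfg <- list(nGenes = as.integer(nGenes),
                timePointsH = as.numeric(timePointsH),
                replicates = as.integer(replicates),
                baselineLog2Mean = baselineLog2Mean,
                baselineLog2Sd = baselineLog2Sd,
                noiseLog2Sd = noiseLog2Sd,
                nSpecificPerStage = as.integer(nSpecificPerStage),
                specificLog2Fc = specificLog2Fc,
                pathwaySize = as.integer(pathwaySize),
                pathwayPeakTimeH = pathwayPeakTimeH,
                pathwayAmplitudeLog2 = pathwayAmplitudeLog2,
                nImmune = as.integer(nImmune),
                immuneOnsetTimeH = immuneOnsetTimeH,
                immuneAmplitudeLog2 = immuneAmplitudeLog2,
                seed = as.integer(seed))
    with(cfg, {
        if (nGenes < 1L) stop("nGenes must be positive")
        if (any(timePointsH <= 0) || is.unsorted(timePointsH, strictly = TRUE))
            stop("timePointsH must be positive and strictly increasing")
        if (replicates < 1L) stop("replicates must be positive")
        if (baselineLog2Sd <= 0 || noiseLog2Sd < 0)
            stop("dispersion parameters must be positive")
        if (nSpecificPerStage < 0L || pathwaySize < 0L || nImmune < 0L)
            stop("planted gene counts must be non-negative")
        if (pathwaySize > 0L && !pathwayPeakTimeH %in% timePointsH)
            stop("pathwayPeakTimeH must be one of timePointsH")
        if (nImmune > 0L && !immuneOnsetTimeH %in% timePointsH)
            stop("immuneOnsetTimeH must be one of timePointsH")
        planted <- 2L * nSpecificPerStage * length(timePointsH) +
            pathwaySize + nImmune
        if (planted > nGenes)
            stop("planted genes (", planted, ") exceed nGenes (", nGenes, ")")
    })
    structure(cfg, class = "SyntheticConfig")
}

# triangular activation in log10-time: peak amplitude at the peak time
# point, declining linearly to 0 at one full log-time span away
.pathwayTrajectory <- function(timePointsH, peakTimeH, amplitude) {
    L <- log10(timePointsH)
    w <- diff(range(L))
    if (w == 0) return(setNames(rep(amplitude, length(L)),
                                timePointsH))
    a <- amplitude * pmax(0, 1 - abs(L - log10(peakTimeH)) / w)
    setNames(a, timePointsH)
}

# immune activation: 0 before onset, then amplitude * (1/2 + ramp/2) rising
# linearly in log10-time from onset to the last time point
.immuneTrajectory <- function(timePointsH, onsetTimeH, amplitude) {
    L <- log10(timePointsH)
    Lo <- log10(onsetTimeH)
    span <- max(L) - Lo
    ramp <- if (span > 0) pmin(1, pmax(0, (L - Lo) / span)) else
        as.numeric(L >= Lo)
    a <- ifelse(L >= Lo, amplitude * (0.5 + 0.5 * ramp), 0)
    setNames(a, timePointsH)
}

#' Generate a synthetic two-group time course with planted ground truth
#'
#' Produces a log2-scale expression matrix: each gene draws one baseline,
#' control samples add replicate noise only, and case samples additionally
#' receive the planted effects — a +/- \code{specificLog2Fc} shift for
#' stage-specific genes at their planted time point, a shared unimodal
#' (triangular in log-time) trajectory for pathway genes, and a rising
#' post-onset trajectory for immune genes.  Deterministic under the
#' configured seed.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{StageExperiment}, log2 scale, design attached) and
#'   \code{truth}, a list of: \code{specificGenes} (data.frame gene_id /
#'   stage / direction), \code{pathwayGenes}, \code{pathwayTrajectory},
#'   \code{immuneGenes}, \code{immuneTrajectory}.
#' @examples
#' sim <- simulateTimecourse(syntheticConfig(nGenes = 300, seed = 7))
#' sim$experiment
#' @export
simulateTimecourse <- function(config) {
    stopifnot(inherits(config, "SyntheticConfig"))
    cfg <- config
    tp <- cfg$timePointsH
    nT <- length(tp)
    geneIds <- sprintf("g%05d", seq_len(cfg$nGenes))

    # deterministic planted-gene layout: up genes, down genes, pathway,
    # immune, then nulls
    nUp <- cfg$nSpecificPerStage * nT
    upIds <- if (nUp) geneIds[seq_len(nUp)] else character()
    downIds <- if (nUp) geneIds[nUp + seq_len(nUp)] else character()
    off <- 2L * nUp
    pathwayIds <- if (cfg$pathwaySize)
        geneIds[off + seq_len(cfg$pathwaySize)] else character()
    off <- off + cfg$pathwaySize
    immuneIds <- if (cfg$nImmune)
        geneIds[off + seq_len(cfg$nImmune)] else character()

    specStage <- rep(tp, each = cfg$nSpecificPerStage)
    truthSpecific <- data.frame(
        gene_id = c(upIds, downIds),
        stage = c(specStage, specStage),
        direction = rep(c("up", "down"), each = nUp),
        stringsAsFactors = FALSE)

    pathTraj <- .pathwayTrajectory(tp, cfg$pathwayPeakTimeH,
                                   cfg$pathwayAmplitudeLog2)
    immTraj <- .immuneTrajectory(tp, cfg$immuneOnsetTimeH,
                                 cfg$immuneAmplitudeLog2)

    # per-gene additive log2 effect in case samples at each time point
    effect <- matrix(0, cfg$nGenes, nT, dimnames = list(geneIds, tp))
    if (nUp) {
        effect[cbind(match(upIds, geneIds), match(specStage, tp))] <-
            cfg$specificLog2Fc
        effect[cbind(match(downIds, geneIds), match(specStage, tp))] <-
            -cfg$specificLog2Fc
    }
    if (length(pathwayIds))
        effect[pathwayIds, ] <- matrix(pathTraj, length(pathwayIds), nT,
                                       byrow = TRUE)
    if (length(immuneIds))
        effect[immuneIds, ] <- matrix(immTraj, length(immuneIds), nT,
                                      byrow = TRUE)

    set.seed(cfg$seed)
    baseline <- rnorm(cfg$nGenes, cfg$baselineLog2Mean, cfg$baselineLog2Sd)

    nSamp <- 2L * nT * cfg$replicates
    design <- expand.grid(replicate = seq_len(cfg$replicates),
                          time_h = tp, group = c("control", "case"),
                          stringsAsFactors = FALSE)
    design <- design[, c("group", "time_h", "replicate")]
    design$sample_id <- sprintf("%s_%gh_r%d",
                                ifelse(design$group == "control", "ctrl",
                                       "case"),
                                design$time_h, design$replicate)

    m <- matrix(0, cfg$nGenes, nSamp,
                dimnames = list(geneIds, design$sample_id))
    for (j in seq_len(nSamp)) {
        eff <- if (design$group[j] == "case")
            effect[, as.character(design$time_h[j])] else 0
        noise <- if (cfg$noiseLog2Sd > 0)
            rnorm(cfg$nGenes, 0, cfg$noiseLog2Sd) else 0
        m[, j] <- baseline + eff + noise
    }

    se <- StageExperiment(m, sampleInfo = design, exprScale = "log2")
    list(experiment = se,
         truth = list(specificGenes = truthSpecific,
                      pathwayGenes = pathwayIds,
                      pathwayTrajectory = pathTraj,
                      immuneGenes = immuneIds,
                      immuneTrajectory = immTraj))
}

#' Generate a synthetic cell-type signature matrix with marker sets
#'
#' Each cell type gets a block of markers expressed strongly in that type
#' and weakly elsewhere, over a log-normal background — a well-conditioned
#' reference for deconvolution and marker-scoring tests.
#'
#' @param nGenes total signature genes.
#' @param nCellTypes number of cell types.
#' @param nMarkersPerType markers per type
#'   (\code{nCellTypes * nMarkersPerType <= nGenes}).
#' @param markerFoldChange linear fold change of a marker in its own type.
#' @param seed integer seed.
#' @return list with \code{signature} (linear-scale genes x cell-types
#'   matrix) and \code{markers} (a \linkS4class{GeneSetList} of marker
#'   genes per type).
#' @export
simulateSignature <- function(nGenes = 200, nCellTypes = 5,
                              nMarkersPerType = 20, markerFoldChange = 16,
                              seed = 1) {
    if (nCellTypes * nMarkersPerType > nGenes)
        stop("more markers than genes")
    set.seed(seed)
    geneIds <- sprintf("sg%04d", seq_len(nGenes))
    types <- sprintf("cellType%d", seq_len(nCellTypes))
    base <- 2^rnorm(nGenes, 5, 1)
    sig <- matrix(rep(base, nCellTypes), nGenes, nCellTypes,
                  dimnames = list(geneIds, types))
    sig <- sig * 2^matrix(rnorm(nGenes * nCellTypes, 0, 0.25),
                          nGenes, nCellTypes)
    markers <- vector("list", nCellTypes)
    names(markers) <- types
    for (k in seq_len(nCellTypes)) {
        idx <- (k - 1L) * nMarkersPerType + seq_len(nMarkersPerType)
        sig[idx, k] <- sig[idx, k] * markerFoldChange
        markers[[k]] <- geneIds[idx]
    }
    list(signature = sig, markers = GeneSetList(markers))
}

#' Generate bulk mixtures of a cell-type signature
#'
#' Bulk expression = signature x proportions, multiplied by log-normal
#' noise (\code{2^N(0, noiseLog2Sd)} per cell).  Linear scale.
#'
#' @param signature linear-scale genes x cell-types matrix (non-negative).
#' @param proportions samples x cell-types matrix; rows non-negative,
#'   summing to 1.  Row names become sample ids (defaults supplied).
#' @param noiseLog2Sd log2-normal noise sd; 0 for noiseless mixtures.
#' @param seed integer seed.
#' @return a linear-scale \linkS4class{StageExperiment} (no design).
#' @export
simulateMixtures <- function(signature, proportions, noiseLog2Sd = 0.1,
                             seed = 1) {
    signature <- as.matrix(signature)
    proportions <- as.matrix(proportions)
    if (ncol(proportions) != ncol(signature))
        stop("proportions columns must match signature cell types")
    if (any(proportions < 0) ||
        any(abs(rowSums(proportions) - 1) > 1e-8))
        stop("proportion rows must be non-negative and sum to 1")
    if (any(signature < 0))
        stop("signature must be non-negative (linear scale)")
    if (is.null(rownames(proportions)))
        rownames(proportions) <- sprintf("mix%03d", seq_len(nrow(proportions)))
    set.seed(seed)
    bulk <- signature %*% t(proportions)
    if (noiseLog2Sd > 0)
        bulk <- bulk * 2^matrix(rnorm(length(bulk), 0, noiseLog2Sd),
                                nrow(bulk), ncol(bulk))
    StageExperiment(bulk, exprScale = "linear")
}
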