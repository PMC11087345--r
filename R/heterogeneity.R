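#' PCA on the most variable genes
#'
#' Ranks genes by their standard deviation across all samples (ties broken
#' by lexicographic gene id), keeps the top \code{nTop}, and runs a PCA on
#' the centered (not scaled) gene vectors.  Component signs are fixed
#' deterministically: each loading vector is flipped, if needed, so its sum
#' is non-negative.
#'
#' @param se a \linkS4class{StageExperiment} (any scale; used as stored).
#' @param nTop number of most-variable genes to keep (default 500).
#' @param k number of components (default 2);
#'   \code{k <= min(nsamples - 1, nTop)}.
#' @return list with \code{scores} (samples x k), \code{explainedVariance}
#'   (fractions, non-increasing) and \code{genes} (the genes used, in rank
#'   order).
#' @export
pcaTopVariable <- function(se, nTop = 500, k = 2) {
    m <- assay(se, "exprs")
    if (ncol(m) < 2L) stop("PCA needs at least 2 samples")
    if (nTop > nrow(m)) stop("nTop exceeds the number of genes")
    if (k > min(ncol(m) - 1L, nTop))
        stop("k exceeds min(nsamples - 1, nTop)")
    sds <- apply(m, 1L, stats::sd)
    ord <- order(-sds, rownames(m))
    keep <- ord[seq_len(nTop)]
    x <- t(m[keep, , drop = FALSE])           # samples x genes
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
    scores <- sweep(pc$x, 2L, flip, `*`)[, seq_len(k), drop = FALSE]
    ev <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
    list(scores = scores, explainedVariance = ev,
         genes = rownames(m)[keep])
}

.splitByTime <- function(cd) {
    split(seq_len(nrow(cd)), as.numeric(cd$time_h))
}

#' Mean between-group Euclidean distance per time point
#'
#' For every time point, the mean over all control x case sample pairs of
#' the Euclidean distance computed over ALL genes.  Invariant to gene and
#' sample order.
#'
#' @param se a \linkS4class{StageExperiment} with design attached; every
#'   time point needs at least one control and one case sample.
#' @return named numeric vector, one distance per time point (ascending
#'   time order).
#' @export
groupDistanceByTime <- function(se) {
    cd <- .requireDesign(se)
    m <- assay(se, "exprs")
    res <- vapply(.splitByTime(cd), function(idx) {
        ctrl <- idx[cd$group[idx] == "control"]
        case <- idx[cd$group[idx] == "case"]
        if (!length(ctrl) || !length(case))
            stop("time point ", cd$time_h[idx[1]],
                 " lacks a control or case sample")
        d <- 0
        for (i in ctrl) for (j in case)
            d <- d + sqrt(sum((m[, i] - m[, j])^2))
        d / (length(ctrl) * length(case))
    }, 0)
    res[order(as.numeric(names(res)))]
}

#' Pearson correlation of group-mean profiles per time point
#'
#' For every time point, Pearson's r between the gene-wise mean control
#' profile and mean case profile, over all genes.
#'
#' @inheritParams groupDistanceByTime
#' @return named numeric vector of correlations per time point.
#' @export
groupCorrelationByTime <- function(se) {
    cd <- .requireDesign(se)
    m <- assay(se, "exprs")
    if (nrow(m) < 3L) stop("need at least 3 genes")
    res <- vapply(.splitByTime(cd), function(idx) {
        ctrl <- idx[cd$group[idx] == "control"]
        case <- idx[cd$group[idx] == "case"]
        if (!length(ctrl) || !length(case))
            stop("time point ", cd$time_h[idx[1]],
                 " lacks a control or case sample")
        a <- rowMeans(m[, ctrl, drop = FALSE])
        b <- rowMeans(m[, case, drop = FALSE])
        if (stats::sd(a) == 0 || stats::sd(b) == 0)
            stop("zero-variance mean profile at time ", cd$time_h[idx[1]],
                 ": correlation undefined")
        stats::cor(a, b)
    }, 0)
    res[order(as.numeric(names(res)))]
}

#' Full heterogeneity report
#'
#' Bundles \code{\link{pcaTopVariable}}, \code{\link{groupDistanceByTime}}
#' and \code{\link{groupCorrelationByTime}}.
#'
#' @inheritParams pcaTopVariable
#' @return list with \code{pca}, \code{distanceByTime},
#'   \code{correlationByTime}.
#' @export
heterogeneityReport <- function(se, nTop = 500, k = 2) {
    list(pca = pcaTopVariable(se, nTop = min(nTop, nrow(se)), k = k),
         distanceByTime = groupDistanceByTime(se),
         correlationByTime = groupCorrelationByTime(se))
}
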