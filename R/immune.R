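#' Per-sample immune infiltration score
#'
#' ssGSEA score of an immune signature gene list in every sample,
#' interpreted as the degree of immune cell infiltration.  Being
#' rank-based it is invariant to monotone per-sample transforms of the
#' expression values.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param immuneSignature character vector of immune signature gene ids
#'   (at least 2 present in the matrix).
#' @inheritParams ssgseaScore
#' @return named numeric vector of per-sample scores.
#' @export
immuneScore <- function(se, immuneSignature, alpha = 0.25,
                        normalize = FALSE) {
    ssgseaScore(se, immuneSignature, alpha = alpha, normalize = normalize)
}

#' Control-vs-case test of a per-sample score at every time point
#'
#' At each time point the two groups are compared with a Shapiro-Wilk-gated
#' test: when both groups pass the normality gate at 0.05 a two-sided
#' Student t-test is used, otherwise a Wilcoxon rank-sum test (groups too
#' small or too degenerate to gate fall to Wilcoxon; two equal constant
#' groups give p = 1).
#'
#' @param scores named numeric vector of per-sample scores (names =
#'   sample ids).
#' @param se the \linkS4class{StageExperiment} carrying the design for
#'   those samples; at least 2 samples per group per time point.
#' @param alpha significance level (default 0.05).
#' @return \code{DataFrame} with columns \code{time_h}, \code{test},
#'   \code{p}, \code{significant}, sorted by time.
#' @export
groupTestByTime <- function(scores, se, alpha = 0.05) {
    cd <- .requireDesign(se)
    ids <- rownames(cd)
    if (!all(ids %in% names(scores)))
        stop("scores missing for some samples")
    tp <- sort(unique(as.numeric(cd$time_h)))
    rows <- lapply(tp, function(t) {
        x <- scores[ids[cd$group == "control" & cd$time_h == t]]
        y <- scores[ids[cd$group == "case" & cd$time_h == t]]
        r <- .gatedGroupTest(x, y)
        data.frame(time_h = t, test = r$test, p = r$p,
                   significant = r$p < alpha, stringsAsFactors = FALSE)
    })
    S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Marker-set ssGSEA scores per cell type
#'
#' Scores every sample against each cell type's marker gene set with
#' ssGSEA; no normalization across cell types is applied (scores are
#' comparable within a cell type across samples, not across cell types).
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param markers a \linkS4class{GeneSetList} of marker sets, one per cell
#'   type (each with at least 2 genes present).
#' @inheritParams ssgseaScore
#' @return a \linkS4class{CellTypeScores} in \code{"marker_ssgsea"} mode.
#' @export
scoreCellTypes <- function(se, markers, alpha = 0.25) {
    sc <- vapply(names(markers), function(nm)
        ssgseaScore(se, markers[[nm]], alpha = alpha),
        numeric(ncol(se)))
    new("CellTypeScores", scores = sc, mode = "marker_ssgsea",
        residuals = numeric())
}

#' Cell-type proportions by non-negative least squares deconvolution
#'
#' Models each bulk sample (linear scale, over the genes shared with the
#' signature) as a non-negative combination of the signature's cell-type
#' columns; coefficients are renormalized to proportions summing to 1 and
#' the per-sample residual norm is reported.
#'
#' @param se bulk \linkS4class{StageExperiment} (log2-stored matrices are
#'   back-transformed to linear).
#' @param signature linear-scale genes x cell-types reference matrix,
#'   non-negative, full column rank on the shared genes.
#' @return a \linkS4class{CellTypeScores} in \code{"deconvolution"} mode
#'   (rows = samples, columns = cell types; \code{residuals} holds the
#'   per-sample residual norm).
#' @export
deconvolve <- function(se, signature) {
    signature <- as.matrix(signature)
    if (any(signature < 0)) stop("signature must be non-negative")
    if (is.null(colnames(signature)))
        stop("signature needs cell-type column names")
    bulk <- linearExprs(se)
    shared <- intersect(rownames(bulk), rownames(signature))
    if (length(shared) < ncol(signature))
        stop("fewer shared genes than cell types")
    A <- signature[shared, , drop = FALSE]
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
        bad <- colnames(A)[qrA$pivot[-seq_len(qrA$rank)]]
        stop("signature is rank-deficient on shared genes; collinear ",
             "column(s): ", paste(bad, collapse = ", "))
    }
    B <- bulk[shared, , drop = FALSE]
    props <- matrix(0, ncol(B), ncol(A),
                    dimnames = list(colnames(B), colnames(A)))
    resid <- numeric(ncol(B))
    names(resid) <- colnames(B)
    for (j in seq_len(ncol(B))) {
        fit <- pracma::lsqnonneg(A, B[, j])
        coef <- pmax(fit$x, 0)
        s <- sum(coef)
        if (s == 0)
            stop("all-zero deconvolution fit for sample ", colnames(B)[j])
        props[j, ] <- coef / s
        resid[j] <- sqrt(sum((B[, j] - A %*% fit$x)^2))
    }
    new("CellTypeScores", scores = props, mode = "deconvolution",
        residuals = resid)
}

# Spearman rho with average ranks plus a two-sided p-value; the default
# t-approximation is swapped for the exact (AS 89) p of cor.test on small
# tie-free samples when pMethod = "exact"
.spearman <- function(x, y, pMethod = "tapprox") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(c(rho = NA_real_, p = NA_real_))
    rx <- rank(x, ties.method = "average")
    ry <- rank(y, ties.method = "average")
    rho <- stats::cor(rx, ry)
    n <- length(x)
    if (pMethod == "exact" && n <= 10 &&
        !anyDuplicated(rx) && !anyDuplicated(ry)) {
        p <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                              exact = TRUE))$p.value
    } else if (abs(rho) >= 1) {
        p <- .Machine$double.xmin
    } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    c(rho = rho, p = max(p, .Machine$double.xmin))
}

#' Gene-by-cell-type Spearman correlation with gene clustering
#'
#' Correlates each gene's expression with each cell type's abundance score
#' over the shared samples (Spearman rho, average ranks; two-sided p by
#' t-approximation, optionally exact for small tie-free samples), then
#' clusters the genes by average-linkage hierarchical clustering on
#' \code{1 - cor(rho rows)} and cuts into \code{nClusters} groups.
#'
#' @param se a \linkS4class{StageExperiment}.
#' @param genes character vector of gene ids present in \code{se}.
#' @param scores a \linkS4class{CellTypeScores} sharing at least 5 samples
#'   with \code{se}.
#' @param nClusters number of gene clusters to cut; default: the number of
#'   distinct stages among \code{geneStages} if supplied, else
#'   \code{min(3, length(genes))}.
#' @param geneStages optional per-gene stage labels (parallel to
#'   \code{genes}) used only for the cluster-count default.
#' @param pMethod \code{"tapprox"} (default) or \code{"exact"}.
#' @return list with \code{rho} and \code{p} (genes x cell types matrices;
#'   constant vectors give NA) and \code{clusters} (named integer vector of
#'   gene cluster labels; NA for genes with no usable correlations).
#' @export
geneCellCorrelation <- function(se, genes, scores, nClusters = NULL,
                                geneStages = NULL,
                                pMethod = c("tapprox", "exact")) {
    pMethod <- match.arg(pMethod)
    stopifnot(is(scores, "CellTypeScores"))
    m <- assay(se, "exprs")
    genes <- as.character(genes)
    if (!all(genes %in% rownames(m)))
        stop("genes absent from the expression matrix: ",
             paste(setdiff(genes, rownames(m)), collapse = ", "))
    sc <- cellTypeScores(scores)
    shared <- intersect(colnames(m), rownames(sc))
    if (length(shared) < 5L) stop("need at least 5 shared samples")
    rho <- matrix(NA_real_, length(genes), ncol(sc),
                  dimnames = list(genes, colnames(sc)))
    pmat <- rho
    for (g in genes) for (ct in colnames(sc)) {
        r <- .spearman(m[g, shared], sc[shared, ct], pMethod)
        rho[g, ct] <- r["rho"]
        pmat[g, ct] <- r["p"]
    }
    if (is.null(nClusters))
        nClusters <- if (!is.null(geneStages))
            length(unique(geneStages)) else min(3L, length(genes))
    usable <- rowSums(is.finite(rho)) >= 2L & apply(rho, 1L, function(v)
        stats::sd(v[is.finite(v)]) > 0)
    clusters <- rep(NA_integer_, length(genes))
    names(clusters) <- genes
    if (sum(usable) >= 2L) {
        rr <- rho[usable, , drop = FALSE]
        d <- stats::as.dist(1 - stats::cor(t(rr)))
        hc <- stats::hclust(d, method = "average")
        k <- min(nClusters, sum(usable))
        clusters[usable] <- stats::cutree(hc, k = k)
    } else if (sum(usable) == 1L) {
        clusters[usable] <- 1L
    }
    list(rho = rho, p = pmat, clusters = clusters)
}
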