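#' Single-sample gene set enrichment scores (ssGSEA)
#'
#' Rank-based per-sample enrichment in the integral (Barbie-style) form.
#' Within each sample, genes are ranked by expression descending with
#' average ranks for ties (walk order on ties is stable by gene id); with
#' absolute ranks r (1..G, the top gene carrying the largest value), the
#' score is \eqn{ES = \sum_i [P_{in}(i) - P_{out}(i)]} where \eqn{P_{in}}
#' is the running sum of \eqn{r^\alpha} over in-set genes normalized by the
#' in-set total and \eqn{P_{out}} the running count of out-of-set genes
#' normalized by \eqn{G - |set|}.  Being rank-based, the score is invariant
#' to monotone transforms of a sample's values.
#'
#' @param se a \linkS4class{StageExperiment} (or numeric matrix).
#' @param geneSet character vector of gene ids; members absent from the
#'   matrix are dropped with a warning, at least 2 must remain, and the set
#'   must be a proper subset of the genes.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize if \code{TRUE}, min-max scale the scores across the
#'   samples of the matrix.
#' @return named numeric vector, one score per sample.
#' @export
ssgseaScore <- function(se, geneSet, alpha = 0.25, normalize = FALSE) {
    m <- if (is(se, "SummarizedExperiment")) assay(se, "exprs") else
        as.matrix(se)
    geneSet <- unique(as.character(geneSet))
    present <- geneSet[geneSet %in% rownames(m)]
    if (length(present) < length(geneSet))
        warning("dropping ", length(geneSet) - length(present),
                " gene set member(s) absent from the matrix")
    if (length(present) < 2L)
        stop("fewer than 2 gene set members present in the matrix")
    G <- nrow(m)
    if (length(present) >= G)
        stop("gene set must be a proper subset of the genes")
    inSet <- rownames(m) %in% present
    nOut <- G - sum(inSet)
    scores <- apply(m, 2L, function(x) {
        # absolute rank, largest value for the top-expressed gene
        r <- rank(x, ties.method = "average")
        ord <- order(-x, rownames(m))
        w <- ifelse(inSet[ord], r[ord]^alpha, 0)
        pin <- cumsum(w) / sum(w)
        pout <- cumsum(!inSet[ord]) / nOut
        sum(pin - pout)
    })
    if (normalize) {
        rng <- range(scores)
        scores <- if (diff(rng) == 0) rep(0, length(scores)) else
            (scores - rng[1]) / diff(rng)
        names(scores) <- colnames(m)
    }
    scores
}

#' ssGSEA trajectory of one gene set over the time course
#'
#' Scores every sample, then summarizes the case samples per time point by
#' their mean score; the peak is the time point with the largest mean
#' (earliest on ties).
#'
#' @param se a \linkS4class{StageExperiment} with design attached.
#' @param geneSet character vector of gene ids.
#' @param name label for the gene set.
#' @inheritParams ssgseaScore
#' @return an \linkS4class{EnrichmentTrajectory}.
#' @export
enrichmentTrajectory <- function(se, geneSet, name = "geneSet",
                                 alpha = 0.25, normalize = FALSE) {
    cd <- .requireDesign(se)
    scores <- ssgseaScore(se, geneSet, alpha = alpha, normalize = normalize)
    case <- cd$group == "case"
    tp <- sort(unique(as.numeric(cd$time_h)))
    byTime <- vapply(tp, function(t)
        mean(scores[case & cd$time_h == t]), 0)
    names(byTime) <- tp
    peak <- tp[which.max(byTime)]
    new("EnrichmentTrajectory", geneSetName = name, sampleScores = scores,
        timeScores = byTime, peakTime = peak)
}

# running-sum ES from the sorted in-set positions; exact classic GSEA
# statistic evaluated only at its candidate extrema (just after each hit
# and just before the next hit)
.gseaES <- function(pos, w, G) {
    m <- length(pos)
    o <- order(pos)
    pos <- pos[o]; w <- w[o]
    pin <- cumsum(w) / sum(w)
    j <- seq_len(m)
    after <- pin - (pos - j) / (G - m)
    before <- c(0, pin[-m]) - (pos - 1 - (j - 1)) / (G - m)
    v <- c(after, before)
    unname(v[which.max(abs(v))])
}

#' Preranked GSEA with gene-set permutation
#'
#' Classic running-sum enrichment score (maximum deviation from zero,
#' in-set increments proportional to |metric|^weight, uniform out-of-set
#' decrements) against a null of random same-size gene sets drawn from the
#' ranked universe.  NES = ES divided by the mean |null ES| over nulls of
#' the same sign; p = (b + 1) / (n_same_sign + 1) where b counts same-sign
#' nulls at least as extreme, so p is never exactly 0.
#'
#' @param ranking named numeric vector of finite metric values (one per
#'   gene); sorted internally by metric descending, ties stable by gene id.
#' @param geneSet character vector; at least 2 members must be present.
#' @param nPerm number of gene-set permutations (default 1000).
#' @param weight metric-weighting exponent (default 1).
#' @param seed integer seed for the permutation draw.
#' @return list with \code{geneSetName}-free fields: \code{es}, \code{nes}
#'   (NA with a flag when no same-sign nulls exist), \code{p},
#'   \code{nPerm}, \code{leadingEdge} (genes contributing to the ES
#'   extremum), \code{nSameSign}.
#' @export
gseaPreranked <- function(ranking, geneSet, nPerm = 1000, weight = 1,
                          seed = 1) {
    if (anyNA(ranking) || any(!is.finite(ranking)))
        stop("ranking values must be finite")
    if (is.null(names(ranking))) stop("ranking must be named by gene id")
    ord <- order(-ranking, names(ranking))
    genes <- names(ranking)[ord]
    metric <- abs(ranking[ord])^weight
    G <- length(genes)
    present <- unique(geneSet[geneSet %in% genes])
    m <- length(present)
    if (m < 1L) stop("no gene set members present in the ranking")
    if (m >= G) stop("gene set must be a proper subset of the ranking")
    pos <- match(present, genes)
    # guard against an all-zero weight vector inside the set
    w <- metric[pos]
    if (sum(w) == 0) w <- rep(1, m)
    es <- .gseaES(pos, w, G)

    set.seed(seed)
    nullEs <- vapply(seq_len(nPerm), function(i) {
        p <- sample.int(G, m)
        wn <- metric[p]
        if (sum(wn) == 0) wn <- rep(1, m)
        .gseaES(p, wn, G)
    }, 0)
    sameSign <- nullEs[sign(nullEs) == sign(es) | es == 0]
    if (!length(sameSign)) {
        nes <- NA_real_
        p <- 1 / (nPerm + 1)
        warning("no same-sign null scores; NES undefined")
    } else {
        nes <- es / mean(abs(sameSign))
        b <- sum(abs(sameSign) >= abs(es))
        p <- (b + 1) / (length(sameSign) + 1)
    }

    # leading edge: hits at or before the ES extremum for positive ES,
    # after it for negative
    o <- order(pos)
    posS <- pos[o]; wS <- w[o]
    pin <- cumsum(wS) / sum(wS)
    j <- seq_along(posS)
    after <- pin - (posS - j) / (G - m)
    before <- c(0, pin[-length(pin)]) - (posS - 1 - (j - 1)) / (G - m)
    if (es >= 0) {
        k <- which.max(after)
        le <- genes[posS[seq_len(k)]]
    } else {
        k <- which.min(before)
        le <- genes[posS[posS >= posS[k]]]
    }
    list(es = es, nes = nes, p = p, nPerm = nPerm,
         nSameSign = length(sameSign), leadingEdge = le)
}

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric test \eqn{P(X \ge k)} of the overlap
#' between a hit list and each gene set (intersected with the universe),
#' with Benjamini-Hochberg correction across the tested sets.  Results are
#' sorted by p-value, then set name.
#'
#' @param hits character vector of hit genes (must be a subset of
#'   \code{universe}).
#' @param universe character vector of all testable genes.
#' @param sets a \linkS4class{GeneSetList}.
#' @return \code{DataFrame} with columns \code{gene_set}, \code{overlap},
#'   \code{set_size} (within universe), \code{universe_size}, \code{hits},
#'   \code{p}, \code{bh_q}, \code{significant_raw} (raw p < 0.05).
#' @export
oraTest <- function(hits, universe, sets) {
    hits <- unique(as.character(hits))
    universe <- unique(as.character(universe))
    if (!length(hits) || !length(universe))
        stop("hits and universe must be non-empty")
    if (!all(hits %in% universe))
        stop("hits must be a subset of the universe")
    N <- length(universe)
    n <- length(hits)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(sets[[nm]], universe)
        K <- length(s)
        k <- length(intersect(s, hits))
        p <- if (K == 0L) 1 else
            stats::phyper(k - 1L, n, N - n, K, lower.tail = FALSE)
        data.frame(gene_set = nm, overlap = k, set_size = K,
                   universe_size = N, hits = n, p = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_set = character(), overlap = integer(),
                          set_size = integer(), universe_size = integer(),
                          hits = integer(), p = numeric())
    out$bh_q <- stats::p.adjust(out$p, method = "BH")
    out$significant_raw <- out$p < 0.05
    out <- out[order(out$p, out$gene_set), , drop = FALSE]
    rownames(out) <- NULL
    S4Vectors::DataFrame(out)
}
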