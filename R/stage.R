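#' Build the per-stage representative expression profile
#'
#' The Tau index divides expression values, so profiles are always built on
#' the LINEAR scale: log2-stored matrices are back-transformed with
#' \code{2^x} first, and the per-stage representative value is the mean of
#' the linear values over the case replicates at that time point
#' (mean-of-linear, not linear-of-mean-log).  Values are floored at
#' \code{epsilon} so that the tau_min ratio stays defined; floored genes
#' are recorded in the profile.
#'
#' @param se a \linkS4class{StageExperiment} with design attached; every
#'   time point needs at least one case sample.
#' @param useGroup which samples define the stages; currently
#'   \code{"case_only"} (stage specificity is a property of the disease
#'   trajectory) or \code{"case_minus_control"} (per-stage mean case minus
#'   mean control difference of linear values, floored at epsilon).
#' @param epsilon floor applied to the profile values (default 1e-8).
#' @return a \linkS4class{StageProfile}.
#' @export
buildStageProfile <- function(se, useGroup = c("case_only",
                                               "case_minus_control"),
                              epsilon = 1e-8) {
    useGroup <- match.arg(useGroup)
    cd <- .requireDesign(se)
    m <- linearExprs(se)
    tp <- sort(unique(as.numeric(cd$time_h)))
    prof <- vapply(tp, function(t) {
        case <- cd$group == "case" & cd$time_h == t
        if (!any(case)) stop("no case samples at time ", t, " h")
        v <- rowMeans(m[, case, drop = FALSE])
        if (useGroup == "case_minus_control") {
            ctrl <- cd$group == "control" & cd$time_h == t
            if (!any(ctrl)) stop("no control samples at time ", t, " h")
            v <- v - rowMeans(m[, ctrl, drop = FALSE])
        }
        v
    }, numeric(nrow(m)))
    prof <- matrix(prof, nrow = nrow(m))
    dimnames(prof) <- list(rownames(m), tp)
    floored <- rownames(prof)[apply(prof < epsilon, 1L, any)]
    if (length(floored))
        message(length(floored), " gene(s) floored at epsilon = ", epsilon)
    prof[prof < epsilon] <- epsilon
    new("StageProfile", values = prof, stages = tp,
        flooredGenes = floored)
}

#' Tau stage-specificity index
#'
#' For each gene with per-stage representative expression \eqn{X_i}
#' (\eqn{i = 1..N} stages, \eqn{X_{max}}/\eqn{X_{min}} the row extremes):
#' \deqn{\tau_{max} = \frac{\sum_{i=1}^{N} (1 - X_i / X_{max})}{N - 1}}
#' \deqn{\tau_{min} = \frac{\sum_{i=1}^{N} (1 - X_{min} / X_i)}{N - 1}}
#' Both lie in [0, 1]: 0 for uniformly expressed genes, 1 for strictly
#' stage-specific ones.  tau_max flags genes specifically HIGH in one
#' stage, tau_min genes specifically LOW in one stage; a gene's specificity
#' is \code{tau = max(tau_max, tau_min)}.  Both indices are invariant to a
#' positive rescaling of the gene's profile.
#'
#' @param profile a \linkS4class{StageProfile} (all values > 0 after
#'   flooring; genes whose profile maximum is not positive are excluded and
#'   reported with a message).
#' @return \code{DataFrame} with columns \code{gene_id}, \code{tau_max},
#'   \code{tau_min}, \code{tau}, \code{assigned_stage} (stage of the
#'   profile maximum when \code{tau_max >= tau_min}, else of the minimum;
#'   earliest stage on ties) and \code{direction} (\code{"up"} /
#'   \code{"down"}), in the gene order of the profile.
#' @export
tauIndex <- function(profile) {
    stopifnot(is(profile, "StageProfile"))
    X <- stageValues(profile)
    N <- length(stages(profile))
    if (N < 2L) stop("Tau needs at least 2 stages")
    drop <- rowSums(X > 0) == 0L | apply(X, 1L, max) <= 0
    if (any(drop))
        message("excluding ", sum(drop), " gene(s) with non-positive profile")
    X <- X[!drop, , drop = FALSE]
    if (any(X <= 0))
        stop("profile contains non-positive values; apply flooring first")
    Xmax <- apply(X, 1L, max)
    Xmin <- apply(X, 1L, min)
    tauMax <- rowSums(1 - X / Xmax) / (N - 1)
    tauMin <- rowSums(1 - Xmin / X) / (N - 1)
    up <- tauMax >= tauMin
    stageIdx <- ifelse(up, apply(X, 1L, which.max), apply(X, 1L, which.min))
    S4Vectors::DataFrame(
        gene_id = rownames(X),
        tau_max = unname(tauMax),
        tau_min = unname(tauMin),
        tau = unname(pmax(tauMax, tauMin)),
        assigned_stage = unname(stages(profile)[stageIdx]),
        direction = unname(ifelse(up, "up", "down")))
}

#' Call stage-specifically expressed genes
#'
#' Filters a \code{\link{tauIndex}} table at a specificity threshold
#' (inclusive: \code{tau >= threshold}) and sorts by descending tau, then
#' gene id.
#'
#' @param tauResults the \code{DataFrame} from \code{\link{tauIndex}}.
#' @param threshold specificity cutoff in (0, 1], default 0.8.
#' @return the filtered, sorted \code{DataFrame} with an added logical
#'   column \code{specific} (all \code{TRUE}).
#' @export
callSpecificGenes <- function(tauResults, threshold = 0.8) {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must be in (0, 1]")
    out <- tauResults[tauResults$tau >= threshold, , drop = FALSE]
    out <- out[order(-out$tau, out$gene_id), , drop = FALSE]
    out$specific <- rep(TRUE, nrow(out))
    out
}

#' Partition the time course at an enrichment peak
#'
#' The progression stage runs up to and including the trajectory's peak
#' time point (argmax of the per-time score, earliest on ties); the
#' remission stage is everything after.  A peak at the final time point
#' yields an empty remission with a warning.
#'
#' @param traj an \linkS4class{EnrichmentTrajectory}.
#' @return a \linkS4class{StagePartition}.
#' @export
partitionStages <- function(traj) {
    ts <- timeScores(traj)
    tp <- as.numeric(names(ts))
    if (length(tp) < 2L) stop("need at least 2 time points")
    peak <- tp[which.max(ts)]
    prog <- tp[tp <= peak]
    rem <- tp[tp > peak]
    if (!length(rem))
        warning("peak at the final time point: remission stage is empty")
    new("StagePartition", peakTime = peak, progression = prog,
        remission = rem)
}

# Shapiro-Wilk-gated two-group test: both groups normal at 0.05 -> Student
# t-test; otherwise (including groups too small or too degenerate to gate)
# Wilcoxon rank-sum.  Two-sided throughout.
.gatedGroupTest <- function(x, y, gateAlpha = 0.05) {
    if (length(x) < 2L || length(y) < 2L)
        stop("need at least 2 samples per group")
    if (stats::sd(c(x, y)) == 0)
        return(list(p = 1, test = "degenerate"))
    normalOk <- function(v) {
        if (length(v) < 3L || stats::sd(v) == 0) return(FALSE)
        stats::shapiro.test(v)$p.value >= gateAlpha
    }
    if (normalOk(x) && normalOk(y)) {
        p <- stats::t.test(x, y)$p.value
        list(p = p, test = "t")
    } else {
        p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                 correct = TRUE))$p.value
        list(p = p, test = "wilcoxon")
    }
}

#' Validate stage-specific genes on an independent cohort
#'
#' For every called gene and every time point of the validation design, a
#' control-vs-case two-group test chosen by a Shapiro-Wilk gate (both
#' groups non-rejecting at 0.05: two-sided Student t-test; otherwise
#' Wilcoxon rank-sum).  A gene is \code{changed} when any raw per-time
#' p-value is below \code{alpha}; BH-corrected calls (across each gene's
#' time points) are emitted alongside for transparency.  Genes absent from
#' the validation matrix are recorded as not testable and excluded from
#' the counts.
#'
#' @param specificGenes \code{DataFrame} from \code{\link{callSpecificGenes}}
#'   (needs \code{gene_id}; \code{assigned_stage} is used for the class
#'   summary when a \code{partition} is supplied).
#' @param valSe validation \linkS4class{StageExperiment} with design
#'   attached, at least 2 samples per group per time point.
#' @param partition optional \linkS4class{StagePartition} from the
#'   discovery time course, used to label genes progression/remission.
#' @param alpha per-test significance level (default 0.05).
#' @return list with \code{perTest} (gene x time long table: \code{gene_id},
#'   \code{time_h}, \code{test}, \code{p}), \code{perGene} (\code{gene_id},
#'   \code{stage_class}, \code{min_p}, \code{changed}, \code{changed_bh},
#'   \code{testable}) and \code{summary} (per stage class: genes tested,
#'   changed, stable, not testable).
#' @export
validateStageGenes <- function(specificGenes, valSe, partition = NULL,
                               alpha = 0.05) {
    cd <- .requireDesign(valSe)
    m <- assay(valSe, "exprs")
    tp <- sort(unique(as.numeric(cd$time_h)))
    for (t in tp) {
        if (sum(cd$group == "control" & cd$time_h == t) < 2L ||
            sum(cd$group == "case" & cd$time_h == t) < 2L)
            stop("validation design needs >= 2 samples per group at ", t, " h")
    }
    genes <- as.character(specificGenes$gene_id)
    classOf <- function(stage) {
        if (is.null(partition) || is.na(stage)) return("unknown")
        if (stage %in% remissionStages(partition)) "remission"
        else if (stage %in% progressionStages(partition)) "progression"
        else "unknown"
    }
    stageClass <- if ("assigned_stage" %in% colnames(specificGenes))
        vapply(as.numeric(specificGenes$assigned_stage), classOf, "")
    else rep("unknown", length(genes))

    perTest <- list()
    perGene <- list()
    for (i in seq_along(genes)) {
        g <- genes[i]
        if (!g %in% rownames(m)) {
            perGene[[i]] <- data.frame(gene_id = g,
                                       stage_class = stageClass[i],
                                       min_p = NA_real_, changed = NA,
                                       changed_bh = NA, testable = FALSE,
                                       stringsAsFactors = FALSE)
            next
        }
        ps <- vapply(tp, function(t) {
            x <- m[g, cd$group == "control" & cd$time_h == t]
            y <- m[g, cd$group == "case" & cd$time_h == t]
            r <- .gatedGroupTest(x, y)
            perTest[[length(perTest) + 1L]] <<-
                data.frame(gene_id = g, time_h = t, test = r$test, p = r$p,
                           stringsAsFactors = FALSE)
            r$p
        }, 0)
        perGene[[i]] <- data.frame(
            gene_id = g, stage_class = stageClass[i], min_p = min(ps),
            changed = any(ps < alpha),
            changed_bh = any(stats::p.adjust(ps, "BH") < alpha),
            testable = TRUE, stringsAsFactors = FALSE)
    }
    perGene <- do.call(rbind, perGene)
    perTest <- if (length(perTest)) do.call(rbind, perTest) else
        data.frame(gene_id = character(), time_h = numeric(),
                   test = character(), p = numeric())
    summ <- do.call(rbind, lapply(split(perGene, perGene$stage_class),
        function(d) data.frame(
            stage_class = d$stage_class[1],
            n_genes = nrow(d),
            n_changed = sum(d$changed, na.rm = TRUE),
            n_stable = sum(!d$changed, na.rm = TRUE),
            n_not_testable = sum(!d$testable),
            stringsAsFactors = FALSE)))
    rownames(summ) <- NULL
    list(perTest = S4Vectors::DataFrame(perTest),
         perGene = S4Vectors::DataFrame(perGene),
         summary = S4Vectors::DataFrame(summ))
}
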