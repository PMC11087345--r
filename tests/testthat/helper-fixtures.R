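# small in-code fixtures shared across test files

# genes x samples StageExperiment with a full two-group design
makeDesignExperiment <- function(m, timePoints, replicates,
                                 exprScale = "log2") {
    design <- expand.grid(replicate = seq_len(replicates),
                          time_h = timePoints,
                          group = c("control", "case"),
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%gh_r%d",
                                ifelse(design$group == "control", "c", "k"),
                                design$time_h, design$replicate)
    stopifnot(ncol(m) == nrow(design))
    colnames(m) <- design$sample_id
    StageExperiment(m, sampleInfo = design, exprScale = exprScale)
}

# StageProfile straight from a genes x stages matrix
makeProfile <- function(values, stages = NULL) {
    if (is.null(stages)) stages <- seq_len(ncol(values))
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
    colnames(values) <- stages
    new("StageProfile", values = values, stages = as.numeric(stages),
        flooredGenes = character())
}

# independent scalar-loop Tau oracle: one gene at a time, plain loops
tauOracle <- function(x) {
    N <- length(x)
    xmax <- max(x); xmin <- min(x)
    smax <- 0; smin <- 0
    for (i in seq_len(N)) {
        smax <- smax + (1 - x[i] / xmax)
        smin <- smin + (1 - xmin / x[i])
    }
    c(tau_max = smax / (N - 1), tau_min = smin / (N - 1))
}
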