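test_that("planted immune up-shift separates case from control scores at zero noise", {
    cfg <- syntheticConfig(nGenes = 200, noiseLog2Sd = 0,
                           nSpecificPerStage = 0, pathwaySize = 0,
                           nImmune = 20, immuneOnsetTimeH = 1, seed = 31)
    sim <- simulateTimecourse(cfg)
    sc <- immuneScore(sim$experiment, sim$truth$immuneGenes)
    cd <- colData(sim$experiment)
    for (t in timePoints(sim$experiment)) {
        ctrl <- sc[rownames(cd)[cd$group == "control" & cd$time_h == t]]
        case <- sc[rownames(cd)[cd$group == "case" & cd$time_h == t]]
        expect_true(min(case) > max(ctrl))
    }
})

test_that("gated group test sizes and powers behave at small n", {
    # a 5-SD shift at n = 5 per group is essentially always detected
    mkSe <- function(reps) makeDesignExperiment(
        matrix(rnorm(6 * reps), 3, 2 * reps,
               dimnames = list(c("a", "b", "c"), NULL)),
        timePoints = 1, replicates = reps)
    runOne <- function(reps, shift) {
        se <- mkSe(reps)
        cd <- colData(se)
        scores <- setNames(rnorm(2 * reps), rownames(cd))
        scores[cd$group == "case"] <- scores[cd$group == "case"] + shift
        as.data.frame(groupTestByTime(scores, se))$significant
    }
    set.seed(37)
    power5 <- mean(replicate(200, runOne(5, 5)))
    expect_gt(power5, 0.95)

    # at n = 3 the Shapiro gate routes ~10% of cases to a rank test that
    # cannot reach p < 0.05, capping power near 0.9
    power3 <- mean(replicate(200, runOne(3, 5)))
    expect_gt(power3, 0.8)

    # null calibration: false-positive rate at or below nominal
    fp <- mean(replicate(300, runOne(5, 0)))
    expect_lt(fp, 0.08)
})

test_that("gated group test handles degenerate and tiny groups", {
    m <- matrix(rnorm(12), 3, 4,
                dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
    se <- makeDesignExperiment(m, timePoints = c(1, 6), replicates = 1)
    scores <- setNames(rnorm(4), colnames(assay(se, "exprs")))
    expect_error(groupTestByTime(scores, se), "at least 2 samples")

    se2 <- makeDesignExperiment(
        matrix(rnorm(12), 3, 4,
               dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4))),
        timePoints = 1, replicates = 2)
    const <- setNames(rep(1, 4), rownames(colData(se2)))
    res <- as.data.frame(groupTestByTime(const, se2))
    expect_equal(res$p, 1)
    expect_false(res$significant)
})

test_that("marker scoring ranks the pure cell type first", {
    sg <- simulateSignature(nGenes = 120, nCellTypes = 4,
                            nMarkersPerType = 15, seed = 41)
    pure <- diag(4)
    colnames(pure) <- colnames(sg$signature)
    rownames(pure) <- sprintf("pure%d", 1:4)
    mix <- simulateMixtures(sg$signature, pure, noiseLog2Sd = 0, seed = 1)
    cts <- scoreCellTypes(mix, sg$markers)
    sc <- cellTypeScores(cts)
    for (k in 1:4)
        expect_equal(unname(which.max(sc[k, ])), k)
})

test_that("identical marker sets give identical score columns", {
    set.seed(43)
    m <- matrix(rnorm(300, 6), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30),
                                sprintf("s%02d", 1:10)))
    se <- StageExperiment(m, exprScale = "log2")
    markers <- GeneSetList(list(t1 = c("g01", "g02", "g03"),
                                t2 = c("g01", "g02", "g03")))
    sc <- cellTypeScores(scoreCellTypes(se, markers))
    expect_equal(sc[, "t1"], sc[, "t2"], tolerance = 1e-12)
})

test_that("marker score is monotone in the mixing weight of its cell type", {
    sg <- simulateSignature(nGenes = 120, nCellTypes = 4,
                            nMarkersPerType = 15, seed = 47)
    w <- seq(0, 1, by = 0.2)
    props <- cbind(w, (1 - w) / 3, (1 - w) / 3, (1 - w) / 3)
    colnames(props) <- colnames(sg$signature)
    rownames(props) <- sprintf("w%d", seq_along(w))
    mix <- simulateMixtures(sg$signature, props, noiseLog2Sd = 0, seed = 1)
    sc <- cellTypeScores(scoreCellTypes(mix, sg$markers))
    expect_true(all(diff(sc[, 1]) > 0))
})

test_that("deconvolution inverts noiseless mixtures exactly", {
    sg <- simulateSignature(seed = 53)
    f <- c(0.2, 0.3, 0.5, 0, 0)
    props <- matrix(f, 1, dimnames = list("m1", colnames(sg$signature)))
    mix <- simulateMixtures(sg$signature, props, noiseLog2Sd = 0, seed = 1)
    dec <- deconvolve(mix, sg$signature)
    expect_equal(unname(cellTypeScores(dec)[1, ]), f, tolerance = 1e-6)
    expect_lt(dec@residuals[[1]], 1e-6)

    oneHot <- matrix(c(0, 0, 1, 0, 0), 1,
                     dimnames = list("m1", colnames(sg$signature)))
    mix2 <- simulateMixtures(sg$signature, oneHot, noiseLog2Sd = 0, seed = 1)
    dec2 <- deconvolve(mix2, sg$signature)
    expect_equal(unname(cellTypeScores(dec2)[1, ]), c(0, 0, 1, 0, 0),
                 tolerance = 1e-6)
})

test_that("deconvolution names collinear signature columns", {
    sig <- cbind(t1 = c(1, 2, 3, 4), t2 = c(2, 4, 6, 8), t3 = c(1, 0, 1, 0))
    rownames(sig) <- sprintf("g%d", 1:4)
    bulk <- StageExperiment(
        matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(rownames(sig), "s1")),
        exprScale = "linear")
    expect_error(deconvolve(bulk, sig), "collinear")
})

test_that("deconvolution stays accurate under log-normal noise", {
    sg <- simulateSignature(seed = 59)
    set.seed(61)
    P <- matrix(rgamma(50 * 5, 1), 50)
    P <- P / rowSums(P)
    colnames(P) <- colnames(sg$signature)
    rownames(P) <- sprintf("m%02d", 1:50)
    mix <- simulateMixtures(sg$signature, P, noiseLog2Sd = 0.1, seed = 67)
    dec <- deconvolve(mix, sg$signature)
    expect_lt(mean(abs(cellTypeScores(dec) - P)), 0.05)
})

test_that("Spearman correlations match a rank-then-Pearson oracle", {
    set.seed(71)
    n <- 12
    m <- matrix(rnorm(5 * n, 6), 5, n,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%02d", 1:n)))
    sc <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(colnames(m), c("t1", "t2", "t3")))
    cts <- new("CellTypeScores", scores = sc, mode = "marker_ssgsea",
               residuals = numeric())
    se <- StageExperiment(m, exprScale = "log2")
    gcc <- geneCellCorrelation(se, rownames(m), cts)
    for (g in rownames(m)) for (ct in colnames(sc)) {
        oracle <- cor(rank(m[g, ]), rank(sc[, ct]))
        expect_equal(gcc$rho[g, ct], oracle, tolerance = 1e-12)
        r <- gcc$rho[g, ct]
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        expect_equal(gcc$p[g, ct], 2 * pt(-abs(tstat), n - 2),
                     tolerance = 1e-12)
    }
})

test_that("a monotone transform of a score column correlates perfectly", {
    set.seed(73)
    n <- 10
    scoreCol <- sort(rnorm(n))
    m <- rbind(gMono = exp(scoreCol), gOther = rnorm(n, 6))
    colnames(m) <- sprintf("s%02d", 1:n)
    sc <- cbind(t1 = scoreCol)
    rownames(sc) <- colnames(m)
    cts <- new("CellTypeScores", scores = sc, mode = "marker_ssgsea",
               residuals = numeric())
    se <- StageExperiment(m, exprScale = "linear")
    gcc <- geneCellCorrelation(se, rownames(m), cts, nClusters = 1)
    expect_equal(gcc$rho["gMono", "t1"], 1, tolerance = 1e-12)
})

test_that("genes tracking the same cell type cluster together", {
    sg <- simulateSignature(nGenes = 150, nCellTypes = 3,
                            nMarkersPerType = 20, seed = 79)
    set.seed(83)
    P <- matrix(rgamma(30 * 3, 1), 30)
    P <- P / rowSums(P)
    colnames(P) <- colnames(sg$signature)
    rownames(P) <- sprintf("m%02d", 1:30)
    mix <- simulateMixtures(sg$signature, P, noiseLog2Sd = 0.05, seed = 89)
    cts <- scoreCellTypes(mix, sg$markers)
    # two markers of cell type 1 and two of cell type 2
    genes <- c(sg$markers[["cellType1"]][1:2], sg$markers[["cellType2"]][1:2])
    gcc <- geneCellCorrelation(mix, genes, cts, nClusters = 2)
    cl <- gcc$clusters
    expect_equal(cl[[1]], cl[[2]])
    expect_equal(cl[[3]], cl[[4]])
    expect_false(cl[[1]] == cl[[3]])
})

test_that("constant vectors yield missing correlations, not errors", {
    n <- 8
    m <- rbind(gConst = rep(2, n), gVar = rnorm(n, 6))
    colnames(m) <- sprintf("s%d", 1:n)
    sc <- cbind(t1 = rnorm(n))
    rownames(sc) <- colnames(m)
    cts <- new("CellTypeScores", scores = sc, mode = "marker_ssgsea",
               residuals = numeric())
    se <- StageExperiment(m, exprScale = "linear")
    gcc <- geneCellCorrelation(se, rownames(m), cts, nClusters = 1)
    expect_true(is.na(gcc$rho["gConst", "t1"]))
    expect_false(is.na(gcc$rho["gVar", "t1"]))
})
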