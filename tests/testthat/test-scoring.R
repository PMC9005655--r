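test_that("weight normalization divides columns by target norms", {
    W <- matrix(c(1, 2, 3, 4), 2, 2,
                dimnames = list(c("d1", "d2"), c("t1", "t2")))
    Y <- cbind(t1 = c(2, 0, 0), t2 = c(3, 4, 0))   # norms 2 and 5
    Wn <- normalizeWeights(W, Y)
    expect_equal(Wn, W / rep(c(2, 5), each = 2))
    # homogeneity: scaling Y by 10 scales What by 1/10
    expect_equal(normalizeWeights(W, 10 * Y), Wn / 10)
    # bias row dropped
    Wb <- rbind(W, "(bias)" = c(9, 9))
    expect_equal(normalizeWeights(Wb, Y), Wn)
    expect_warning(Wz <- normalizeWeights(W, cbind(Y[, 1], 0)), "zero-norm")
    expect_equal(unname(Wz[, 2]), c(0, 0))
    expect_error(normalizeWeights(W, Y[, 1, drop = FALSE]), "share")
})

test_that("activity score matches its closed forms", {
    # single-target regulon is always fully active
    expect_equal(activityScore(5, 0.3), 1)
    # equal weights: (T+1)/(2T)
    expect_equal(activityScore(c(3, 2, 1), rep(0.2, 3)), 2/3)
    expect_equal(activityScore(c(9, 1, 5, 7), rep(1, 4)), 5/8)
    # one-hot regulon: 1 when its target is the most expressed, 1/T when least
    expect_equal(activityScore(c(10, 1, 1), c(1, 0, 0)), 1)
    expect_equal(activityScore(c(0, 5, 6), c(1, 0, 0)), 1/3)
    # negative weights accumulate by magnitude
    expect_equal(activityScore(c(10, 1, 1), c(-1, 0, 0)), 1)
    # empty regulon -> sentinel
    expect_true(is.na(activityScore(c(1, 2), c(0, 0))))
    # ascending flag reverses the ranking
    expect_equal(activityScore(c(10, 1, 1), c(1, 0, 0), ascending = TRUE),
                 1/3)
})

test_that("activity score is invariant to rank-preserving expression scaling", {
    set.seed(5)
    for (i in 1:25) {
        e <- runif(6)
        w <- runif(6) * rbinom(6, 1, 0.7)
        if (all(w == 0)) next
        s <- activityScore(e, w)
        expect_equal(activityScore(3.2 * e, w), s)
        expect_gte(s, 0); expect_lte(s, 1)
    }
})

test_that("activity matrices are per-state, bounded, and rank-driven", {
    # two targets; driver regulon is one-hot on t1.
    # state A: t1 most expressed in every cell -> score 1
    # state B: t1 least expressed -> score 1/T = 1/2
    expr <- rbind(tf = c(5, 6, 5, 6),
                  t1 = c(9, 9, 1, 1),
                  t2 = c(1, 2, 8, 7))
    colnames(expr) <- paste0("c", 1:4)
    ds <- GRNExperiment(expr, phenotype = c("A", "A", "B", "B"),
                        phenotypeOrder = c("A", "B"), drivers = "tf")
    W <- matrix(c(2, 1e-9, 0, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("tf", "(bias)"), c("t1", "t2")))
    wset <- new("IncidenceMatrixSet", weights = list(W, W),
                driverGenes = "tf", targetGenes = c("t1", "t2"),
                phenotypeOrder = c("A", "B"), lambda1 = 0, lambda2 = 0,
                fit = list())
    filt <- filterRegulons(wset)   # keeps only the dominant t1 weight
    act <- activityMatrix(ds, wset, filt)
    expect_equal(unname(activityScores(act, "A")[, "tf"]), c(1, 1))
    expect_equal(unname(activityScores(act, "B")[, "tf"]), c(1/2, 1/2))
    # unfiltered: both targets in the regulon, all entries within [0, 1]
    act2 <- activityMatrix(ds, wset)
    for (lv in c("A", "B")) {
        A <- activityScores(act2, lv)
        expect_true(all(A >= 0 & A <= 1, na.rm = TRUE))
    }
    # duplicated cells give identical score rows
    expect_equal(activityScores(act2, "A")[1, ],
                 activityScores(act2, "A")[1, ])
})

test_that("regulon filtering keeps the smallest prefix reaching the fraction", {
    mkset <- function(col) {
        W <- rbind(matrix(col, ncol = 1), "(bias)" = 0)
        rownames(W) <- c(paste0("d", seq_along(col)), "(bias)")
        colnames(W) <- "t1"
        new("IncidenceMatrixSet", weights = list(W),
            driverGenes = paste0("d", seq_along(col)), targetGenes = "t1",
            phenotypeOrder = "only", lambda1 = 0, lambda2 = 0, fit = list())
    }
    # squared weights 9,1,1,1: shares .75, .833, .917 -> keep 3
    f <- filterRegulons(mkset(c(3, 1, 1, 1)))
    expect_equal(sum(f@keepDrivers[[1]]), 3L)
    expect_true(all(f@keepDrivers[[1]][1:3, 1]))
    # a single non-zero driver is kept exactly
    f1 <- filterRegulons(mkset(c(0, 2, 0)))
    expect_equal(which(f1@keepDrivers[[1]][, 1]), c(d2 = 2L))
    # ten equal weights: cumulative hits 0.9 at the ninth
    f9 <- filterRegulons(mkset(rep(1, 10)))
    expect_equal(sum(f9@keepDrivers[[1]]), 9L)
    # all-zero column -> empty driver set
    f0 <- filterRegulons(mkset(c(0, 0)))
    expect_equal(sum(f0@keepDrivers[[1]]), 0L)
    # monotone: raising the fraction keeps a superset
    w <- c(3, 2, 2, 1, 0.5, 0.1)
    lo <- filterRegulons(mkset(w), 0.6)@keepDrivers[[1]]
    hi <- filterRegulons(mkset(w), 0.95)@keepDrivers[[1]]
    expect_true(all(hi[lo]))
})

test_that("poorly fitted targets are dropped at the documented threshold", {
    r2 <- c(a = 0.9, b = 0.69, c = 0.7)
    expect_equal(unname(dropPoorTargets(r2)), c(TRUE, FALSE, TRUE))
    expect_equal(unname(dropPoorTargets(r2, threshold = 0)), rep(TRUE, 3))
    expect_warning(m <- dropPoorTargets(c(0.1, 0.2)), "threshold")
    expect_equal(unname(m), c(FALSE, FALSE))
    # matrix input averages across phenotypes
    expect_equal(unname(dropPoorTargets(cbind(c(0.9, 0.5), c(0.6, 0.5)))),
                 c(TRUE, FALSE))
})

test_that("score histograms are normalized with a right-closed last bin", {
    d <- scoreDistribution(rep(0.5, 7), nBins = 2L)
    expect_equal(d@prob, c(0, 1))
    # uniform grid over [0,1): every one of 10 bins gets a tenth
    g <- scoreDistribution(seq(0, 0.99, length.out = 100), nBins = 10L)
    expect_equal(g@prob, rep(0.1, 10))
    # a score of exactly 1 lands in the last bin
    expect_equal(scoreDistribution(c(1, 1), nBins = 4L)@prob,
                 c(0, 0, 0, 1))
    set.seed(2)
    expect_equal(sum(scoreDistribution(runif(57))@prob), 1)
    expect_error(scoreDistribution(numeric(0)), "no scores")
    expect_error(scoreDistribution(c(0.2, 1.4)), "0, 1")
})

test_that("total variation and its minmax generalisation agree", {
    mk <- function(p) new("ScoreDistribution",
                          edges = seq(0, 1, length.out = length(p) + 1L),
                          prob = p / sum(p), label = "")
    expect_equal(totalVariation(mk(c(1, 3)), mk(c(1, 3))), 0)
    expect_equal(totalVariation(mk(c(1, 0)), mk(c(0, 1))), 1)
    expect_equal(totalVariation(mk(c(0.5, 0.5)), mk(c(0.75, 0.25))), 0.25)
    expect_error(totalVariation(mk(c(1, 1)), mk(c(1, 1, 1))), "binned")
    # K = 2 degeneracy, across 1000 random pairs, to 1e-12
    set.seed(8)
    for (i in 1:1000) {
        P <- mk(runif(20)); Q <- mk(runif(20))
        expect_equal(minmaxTV(list(P, Q)), totalVariation(P, Q),
                     tolerance = 1e-12)
    }
    expect_equal(minmaxTV(list(mk(1:3), mk(1:3), mk(1:3))), 0)
    # three mutually disjoint one-hots over three bins
    expect_equal(minmaxTV(list(mk(c(1, 0, 0)), mk(c(0, 1, 0)),
                               mk(c(0, 0, 1)))), 1)
    expect_error(minmaxTV(list(mk(c(1, 0)))), "two distributions")
})

test_that("dissimilarity table flags shifted regulons and missing clusters", {
    A1 <- matrix(c(rep(0.9, 4), rep(0.5, 4)), 4, 2,
                 dimnames = list(paste0("a", 1:4), c("tfX", "tfY")))
    A2 <- matrix(c(rep(0.1, 4), rep(0.5, 4)), 4, 2,
                 dimnames = list(paste0("b", 1:4), c("tfX", "tfY")))
    act <- new("ActivityScoreSet", scores = list(s1 = A1, s2 = A2),
               phenotypeOrder = c("s1", "s2"))
    tab <- dissimilarityTable(act)
    expect_equal(dim(tab), c(2L, 1L))
    # tfX flips activity entirely between states; tfY is unchanged
    expect_equal(unname(tab["tfX", "all"]), 1)
    expect_equal(unname(tab["tfY", "all"]), 0)
    expect_true(all(tab >= 0 & tab <= 1))
    # a cluster unseen in one phenotype stays NA, with a warning
    clusters <- c(stats::setNames(rep("c1", 4), rownames(A1)),
                  stats::setNames(c("c1", "c1", "c2", "c2"), rownames(A2)))
    expect_warning(tab2 <- dissimilarityTable(act, clusters), "empty")
    expect_true(all(is.na(tab2[, "c2"])))
    expect_false(anyNA(tab2[, "c1"]))
    # identical score vectors across phenotypes -> zero column
    actSame <- new("ActivityScoreSet",
                   scores = list(s1 = A1,
                                 s2 = `rownames<-`(A1, paste0("b", 1:4))),
                   phenotypeOrder = c("s1", "s2"))
    expect_equal(unname(dissimilarityTable(actSame)[, 1]), c(0, 0))
    # single phenotype refuses
    expect_error(dissimilarityTable(
        new("ActivityScoreSet", scores = list(s1 = A1),
            phenotypeOrder = "s1")), "two phenotypes")
})
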