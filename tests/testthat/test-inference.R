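test_that("soft-thresholding matches its closed form", {
    expect_equal(softThreshold(2.0, 0.5), 1.5)
    expect_equal(softThreshold(-0.3, 0.5), 0)
    expect_equal(softThreshold(-2.0, 1.0), -1.0)
    expect_equal(softThreshold(c(-1, 0, 3), 1), c(0, 0, 2))
    expect_error(softThreshold(1, -1))
})

test_that("joint objective agrees with direct arithmetic", {
    # 1 TF, 1 target, 2 states, 2 cells per state: every sum by hand
    expr <- matrix(c(1, 2, 3, 4,    # TF
                     2, 3, 1, 0),   # target
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("tf", "tg"), paste0("c", 1:4)))
    ds <- GRNExperiment(expr, phenotype = c("A", "A", "B", "B"),
                        phenotypeOrder = c("A", "B"), drivers = "tf")
    mkW <- function(w1, b1, w2, b2)
        new("IncidenceMatrixSet",
            weights = list(matrix(c(w1, b1), 2, 1,
                                  dimnames = list(c("tf", "(bias)"), "tg")),
                           matrix(c(w2, b2), 2, 1,
                                  dimnames = list(c("tf", "(bias)"), "tg"))),
            driverGenes = "tf", targetGenes = "tg",
            phenotypeOrder = c("A", "B"), lambda1 = 0, lambda2 = 0,
            fit = list())
    # all-zero weights on zero targets -> 0
    expr0 <- expr; expr0["tg", ] <- 0
    ds0 <- GRNExperiment(expr0, phenotype = c("A", "A", "B", "B"),
                         phenotypeOrder = c("A", "B"), drivers = "tf")
    expect_equal(jointObjective(mkW(0, 0, 0, 0), ds0, 5, 5), 0)
    # hand case: w1=0.5,b1=1 ; w2=-1,b2=2 ; lambda1=0.1, lambda2=2
    # state A residuals: 2-(0.5*1+1)=0.5 ; 3-(0.5*2+1)=1
    # state B residuals: 1-(-3+2)=2 ; 0-(-4+2)=2
    # loss = .5*(.25+1) + .5*(4+4) = 0.625 + 4 = 4.625
    # l1   = 0.1*(0.5+1) = 0.15 (bias exempt)
    # sim  = 2*(0.5-(-1))^2 = 4.5
    expect_equal(jointObjective(mkW(0.5, 1, -1, 2), ds, 0.1, 2),
                 4.625 + 0.15 + 4.5)
    # K = 1 reduces to the plain LASSO objective
    dsA <- ds[, 1:2]
    S4Vectors::metadata(dsA)$phenotypeOrder <- "A"
    wA <- new("IncidenceMatrixSet",
              weights = list(matrix(c(0.5, 1), 2, 1)),
              driverGenes = "tf", targetGenes = "tg", phenotypeOrder = "A",
              lambda1 = 0.1, lambda2 = 0, fit = list())
    expect_equal(jointObjective(wA, dsA, 0.1, 99), 0.625 + 0.05)
})

test_that("huge lambda1 shrinks every non-bias weight to zero", {
    ds <- makeToyDataset(seed = 21L)
    fit <- fitJointGRNs(ds, lambda1 = 1e6, lambda2 = 0.1)
    for (lv in phenotypeOrder(ds)) {
        W <- incidenceMatrix(fit$weights, lv, withBias = FALSE)
        expect_true(all(W == 0))
    }
})

test_that("lambda2 = 0 matches an independent coordinate-descent LASSO oracle", {
    truth <- generateGRNChain(K = 2, m = 3, n = 2, noiseSd = 1, seed = 31)
    ds <- simulateExpression(truth, cellsPerState = 50, seed = 32)
    lambda1 <- 0.05
    fit <- fitJointGRNs(ds, lambda1, 0,
                        solverConfig(maxEpochs = 50000L, tol = 1e-15))
    for (lv in phenotypeOrder(ds)) {
        X <- driverMatrix(ds, lv)
        Y <- targetMatrix(ds, lv)
        W <- incidenceMatrix(fit$weights, lv)
        for (j in seq_len(ncol(Y))) {
            o <- lassoCDOracle(X, Y[, j], lambda1)
            expect_equal(unname(W[1:3, j]), o$w, tolerance = 1e-4)
            expect_equal(unname(W[4L, j]), o$b, tolerance = 1e-4)
        }
    }
})

test_that("huge lambda2 forces the state matrices to consensus", {
    truth <- generateGRNChain(K = 2, m = 3, n = 2, noiseSd = 1, seed = 41)
    ds <- simulateExpression(truth, cellsPerState = 50, seed = 42)
    fit <- fitJointGRNs(ds, 1e-3, 1e6,
                        solverConfig(maxEpochs = 5000L, tol = 1e-12))
    d <- abs(incidenceMatrix(fit$weights, "state1", withBias = FALSE) -
             incidenceMatrix(fit$weights, "state2", withBias = FALSE))
    expect_lt(max(d), 1e-3)
})

test_that("objective trace is non-increasing in cyclic mode", {
    ds <- makeToyDataset(m = 4L, n = 3L, seed = 51L)
    fit <- fitJointGRNs(ds, 1e-2, 1e-2, solverConfig(schedule = "cyclic"))
    tr <- fit$report@objectiveTrace
    expect_gt(length(tr), 1L)
    expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
})

test_that("sparsity is monotone along a lambda1 ladder", {
    ds <- makeToyDataset(m = 5L, n = 4L, cellsPerState = 40L, seed = 61L)
    nnz <- sapply(c(1e-3, 1e-1, 1e1, 1e3, 1e5), function(l1) {
        fit <- fitJointGRNs(ds, l1, 1e-2, solverConfig(seed = 2L))
        sum(sapply(phenotypeOrder(ds), function(lv)
            sum(abs(incidenceMatrix(fit$weights, lv, withBias = FALSE))
                > 1e-8)))
    })
    expect_true(all(diff(nnz) <= 0))
})

test_that("cell order within a phenotype does not change the fit", {
    ds <- makeToyDataset(m = 4L, n = 3L, seed = 71L)
    cfg <- solverConfig(schedule = "cyclic")
    f1 <- fitJointGRNs(ds, 1e-2, 1e-2, cfg)
    set.seed(1)
    perm <- unlist(lapply(phenotypeOrder(ds), function(lv)
        sample(which(cellPhenotypes(ds) == lv))))
    f2 <- fitJointGRNs(ds[, perm], 1e-2, 1e-2, cfg)
    for (lv in phenotypeOrder(ds))
        expect_equal(incidenceMatrix(f1$weights, lv),
                     incidenceMatrix(f2$weights, lv), tolerance = 1e-8)
})

test_that("random-schedule fits are reproducible for a fixed seed", {
    ds <- makeToyDataset(seed = 81L)
    f1 <- fitJointGRNs(ds, 1e-2, 1e-2, solverConfig(seed = 9L))
    f2 <- fitJointGRNs(ds, 1e-2, 1e-2, solverConfig(seed = 9L))
    expect_identical(f1$weights@weights, f2$weights@weights)
})

test_that("linear prediction matches matrix arithmetic", {
    # bias-only network predicts the bias everywhere
    W <- matrix(c(0, 0, 3, 0, 0, -1), 3, 2,
                dimnames = list(c("d1", "d2", "(bias)"), c("t1", "t2")))
    X <- matrix(rnorm(10), 5, 2)
    P <- predictTargets(W, X)
    expect_equal(unname(P[, 1]), rep(3, 5))
    # identity-like single edge
    W1 <- matrix(c(1, 0), 2, 1)
    expect_equal(unname(predictTargets(W1, matrix(1:4, 4, 1))[, 1]),
                 as.numeric(1:4))
    # hand 2x2 product
    Wh <- matrix(c(1, 2, 0.5, -1, 0, 3), 3, 2)
    Xh <- matrix(c(1, 0, 2, 1), 2, 2)
    expect_equal(predictTargets(Wh, Xh), cbind(Xh, 1) %*% Wh)
    expect_error(predictTargets(Wh, matrix(0, 2, 4)), "mismatch")
})

test_that("adjusted R-squared matches its closed form", {
    y <- rnorm(10)
    expect_equal(adjustedR2(y, y, 3), 1)
    # predicting the mean: R2 = 0, adjusted = -p/(n-p-1) = -1/8
    expect_equal(adjustedR2(y, rep(mean(y), 10), 1), -1/8)
    # 4-point simple regression, by closed form
    x <- c(0, 1, 2, 3); yt <- c(0, 1, 1, 3)
    fitLm <- lm(yt ~ x)
    expect_equal(adjustedR2(yt, fitted(fitLm), 1),
                 summary(fitLm)$adj.r.squared)
    expect_true(is.na(adjustedR2(rep(2, 10), rnorm(10), 1)))
})

test_that("cross-validation table covers the grid and respects trivial grids", {
    ds <- makeToyDataset(m = 3L, n = 2L, cellsPerState = 30L, seed = 91L)
    cfg <- solverConfig(maxEpochs = 200L, tol = 1e-4)
    cv1 <- crossValidate(ds, grid1 = 1e-2, grid2 = 1e-3, folds = 2L,
                         seed = 1L, config = cfg)
    expect_equal(cv1$lambda1, 1e-2)
    expect_equal(cv1$lambda2, 1e-3)
    cv <- crossValidate(ds, folds = 2L, seed = 1L, config = cfg)
    expect_equal(nrow(cv$table), 25L)
    expect_true(all(c(cv$lambda1, cv$lambda2) %in% 10^(-5:-1)))
    expect_error(crossValidate(ds, numeric(0), 1e-2), "empty")
})

test_that("similar states make CV prefer a larger similarity penalty", {
    # identical networks across states vs independently drawn networks
    same <- generateGRNChain(K = 3, m = 4, n = 3, pFlip = 0, pToZero = 0,
                             noiseSd = 3, seed = 101)
    mix <- generateGRNChain(K = 3, m = 4, n = 3, pFlip = 0.5, pToZero = 0.5,
                            pKeepZero = 0.2, noiseSd = 3, seed = 101)
    cfg <- solverConfig(maxEpochs = 300L, tol = 1e-6)
    grid2 <- c(1e-3, 1e3)
    pick <- function(truth) {
        ds <- simulateExpression(truth, cellsPerState = 40, seed = 102)
        crossValidate(ds, grid1 = 1e-2, grid2 = grid2, folds = 3L,
                      seed = 3L, config = cfg)$lambda2
    }
    expect_gte(pick(same), pick(mix))
})
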