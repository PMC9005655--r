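#' Select penalty weights by repeated stratified cross-validation
#'
#' Evaluates every (lambda1, lambda2) pair on \code{folds} repeated
#' phenotype-stratified 80/20 splits, scoring each by the mean held-out
#' adjusted R-squared across targets and states, and returns the argmax pair
#' together with the full table. The default grid for both penalties is the
#' polynomial set \{1e-5, 1e-4, 1e-3, 1e-2, 1e-1\}.
#'
#' @param ds a [GRNExperiment-class].
#' @param grid1,grid2 candidate values for lambda1 and lambda2.
#' @param folds number of repeated splits (>= 2).
#' @param ratio training fraction of each split.
#' @param seed integer seed (fans out to one seed per split).
#' @param config a [solverConfig()] for the inner fits.
#' @return list with \code{lambda1}, \code{lambda2} and \code{table}
#'   (a data.frame of mean scores per pair).
#' @export
crossValidate <- function(ds, grid1 = 10^(-5:-1), grid2 = 10^(-5:-1),
                          folds = 5L, ratio = 0.8, seed = 1L,
                          config = solverConfig()) {
    stopifnot(folds >= 2L)
    if (!length(grid1) || !length(grid2)) stop("empty penalty grid")
    grid <- expand.grid(lambda1 = grid1, lambda2 = grid2,
                        KEEP.OUT.ATTRS = FALSE)
    score <- matrix(NA_real_, nrow(grid), folds)
    m <- length(driverGenes(ds))
    for (f in seq_len(folds)) {
        sp <- splitTrainTest(ds, ratio, deriveSeed(seed, "cv", f))
        pre <- .precomputeStates(ds, trainCells(sp))
        for (g in seq_len(nrow(grid))) {
            sol <- .fitCore(pre, grid$lambda1[g], grid$lambda2[g], config)
            wset <- new("IncidenceMatrixSet", weights = sol$W,
                        driverGenes = pre$drivers, targetGenes = pre$targets,
                        phenotypeOrder = pre$order,
                        lambda1 = grid$lambda1[g], lambda2 = grid$lambda2[g],
                        fit = list())
            r2 <- goodnessOfFit(ds, wset, testCells(sp))
            score[g, f] <- mean(r2, na.rm = TRUE)
        }
    }
    grid$meanAdjustedR2 <- rowMeans(score)
    if (all(!is.finite(grid$meanAdjustedR2)))
        stop("no held-out adjusted R^2 could be computed; ",
             "too few validation cells per phenotype")
    best <- which.max(grid$meanAdjustedR2)
    list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
         table = grid)
}
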