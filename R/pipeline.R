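#' Derive a stage seed from the run seed
#'
#' Every stochastic stage of a run draws its own seed deterministically from
#' the single run seed, so one integer reproduces a whole pipeline. The
#' derivation is \code{(seed * 131 + 1000 * stageIndex + k) mod (2^31 - 1)}
#' with a fixed stage table.
#'
#' @param seed run seed (integer).
#' @param stage one of \code{"generate"}, \code{"simulate"}, \code{"split"},
#'   \code{"solver"}, \code{"cv"}, \code{"cluster"}.
#' @param k within-stage counter (e.g. fold number).
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stage, k = 0L) {
    stages <- c(generate = 1L, simulate = 2L, split = 3L, solver = 4L,
                cv = 5L, cluster = 6L)
    if (!stage %in% names(stages)) stop("unknown stage: ", stage)
    as.integer((as.numeric(seed) * 131 + 1000 * stages[[stage]] + k) %%
               2147483647)
}

.writeConfig <- function(config, dir) {
    config$package_version <- as.character(utils::packageVersion("jointGRN"))
    jsonlite::write_json(config, file.path(dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate a synthetic benchmark run directory
#'
#' Generates a ground-truth chain and the matching expression with
#' [generateGRNChain()] / [simulateExpression()], and writes the dataset
#' (TSV formats of [writeGRNExperiment()]), one \code{truth_state<k>.tsv}
#' ternary matrix per state, and a \code{run_config.json} capturing every
#' parameter and seed.
#'
#' @param dir output run directory.
#' @param K,m,n,cellsPerState,noiseSd generator settings (paper-scale
#'   defaults: 5 states, 50 TFs, 20 targets, 1000 cells/state).
#' @param seed run seed; stage seeds derive from it via [deriveSeed()].
#' @return \code{dir}, invisibly.
#' @export
runSimulate <- function(dir, K = 5L, m = 50L, n = 20L,
                        cellsPerState = 1000L, noiseSd = 4, seed = 1L) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    truth <- generateGRNChain(K = K, m = m, n = n, noiseSd = noiseSd,
                              seed = deriveSeed(seed, "generate"))
    ds <- simulateExpression(truth, cellsPerState,
                             seed = deriveSeed(seed, "simulate"))
    writeGRNExperiment(ds, dir)
    for (k in seq_len(K)) {
        W <- truth@networks[[k]]
        data.table::fwrite(data.frame(driver = rownames(W), W,
                                      check.names = FALSE),
                           file.path(dir, sprintf("truth_state%d.tsv", k)),
                           sep = "\t")
    }
    .writeConfig(list(subcommand = "simulate", K = K, m = m, n = n,
                      cellsPerState = cellsPerState, noiseSd = noiseSd,
                      seed = seed), dir)
    invisible(dir)
}

#' Read back a run directory written by [runSimulate()]
#' @param dir the run directory.
#' @return a [GRNExperiment-class].
#' @export
readRunDataset <- function(dir) {
    readGRNExperiment(file.path(dir, "expression.tsv"),
                      file.path(dir, "metadata.tsv"),
                      file.path(dir, "drivers.txt"),
                      readLines(file.path(dir, "phenotype_order.txt")))
}

#' Fit joint networks end to end and write a run directory
#'
#' Loads (or takes) a dataset, optionally selects penalties by
#' [crossValidate()], fits with [fitJointGRNs()] on a stratified training
#' split, and writes one incidence TSV per phenotype (rows drivers +
#' \code{__bias__}), a JSON sidecar with the penalties, seed and
#' convergence info, the fit report, and \code{run_config.json}.
#'
#' @param ds a [GRNExperiment-class], or a run directory readable by
#'   [readRunDataset()].
#' @param dir output directory.
#' @param lambda1,lambda2 penalty weights; if either is \code{NULL} both are
#'   chosen by cross-validation over \code{grid}.
#' @param grid candidate penalty values for the CV path.
#' @param ratio train fraction of the evaluation split.
#' @param seed run seed.
#' @param config a [solverConfig()]; its seed is re-derived from \code{seed}.
#' @return list with \code{weights}, \code{report}, \code{dir} (invisible).
#' @export
runInference <- function(ds, dir, lambda1 = 1e-2, lambda2 = NULL,
                         grid = 10^(-5:-1), ratio = 0.8, seed = 1L,
                         config = solverConfig()) {
    if (is.character(ds)) ds <- readRunDataset(ds)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    config$seed <- deriveSeed(seed, "solver")
    cv <- NULL
    if (is.null(lambda1) || is.null(lambda2)) {
        cv <- crossValidate(ds, grid, grid, seed = deriveSeed(seed, "cv"),
                            config = config)
        lambda1 <- cv$lambda1
        lambda2 <- cv$lambda2
    }
    split <- splitTrainTest(ds, ratio, deriveSeed(seed, "split"))
    fit <- fitJointGRNs(ds, lambda1, lambda2, config, split)
    writeIncidenceMatrices(fit$weights, dir)
    r2 <- fit$report@adjustedR2
    data.table::fwrite(data.frame(target = rownames(r2), r2,
                                  check.names = FALSE),
                       file.path(dir, "adjusted_r2.tsv"), sep = "\t")
    .writeConfig(list(subcommand = "infer", lambda1 = lambda1,
                      lambda2 = lambda2, ratio = ratio, seed = seed,
                      schedule = config$schedule, tol = config$tol,
                      maxEpochs = config$maxEpochs,
                      medianAdjustedR2 = fit$report@medianAdjustedR2,
                      crossValidated = !is.null(cv)), dir)
    invisible(list(weights = fit$weights, report = fit$report, dir = dir))
}

#' Write / read incidence matrices as one TSV per phenotype
#'
#' Rows are the drivers plus a final \code{__bias__} row; columns are the
#' targets. A \code{weights.json} sidecar records the penalties, phenotype
#' order and solver diagnostics.
#'
#' @param wset an [IncidenceMatrixSet-class].
#' @param dir directory to write into.
#' @return \code{dir} invisibly ([writeIncidenceMatrices()]); an
#'   [IncidenceMatrixSet-class] ([readIncidenceMatrices()]).
#' @export
writeIncidenceMatrices <- function(wset, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(wset@phenotypeOrder)) {
        W <- wset@weights[[k]]
        rn <- c(wset@driverGenes, "__bias__")
        data.table::fwrite(data.frame(driver = rn, W, check.names = FALSE),
                           file.path(dir, sprintf("incidence_%s.tsv",
                                                  wset@phenotypeOrder[k])),
                           sep = "\t")
    }
    jsonlite::write_json(
        list(lambda1 = wset@lambda1, lambda2 = wset@lambda2,
             phenotypeOrder = wset@phenotypeOrder, fit = wset@fit),
        file.path(dir, "weights.json"), auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname writeIncidenceMatrices
#' @param dir directory containing \code{incidence_*.tsv} and
#'   \code{weights.json}.
#' @export
readIncidenceMatrices <- function(dir) {
    side <- jsonlite::read_json(file.path(dir, "weights.json"),
                                simplifyVector = TRUE)
    ord <- side$phenotypeOrder
    weights <- lapply(ord, function(lv) {
        df <- data.table::fread(file.path(dir, sprintf("incidence_%s.tsv", lv)),
                                data.table = FALSE)
        W <- as.matrix(df[, -1L, drop = FALSE])
        rn <- df[[1L]]
        rn[rn == "__bias__"] <- "(bias)"
        rownames(W) <- rn
        W
    })
    drv <- rownames(weights[[1L]])
    drv <- drv[drv != "(bias)"]
    new("IncidenceMatrixSet", weights = weights, driverGenes = drv,
        targetGenes = colnames(weights[[1L]]), phenotypeOrder = ord,
        lambda1 = side$lambda1, lambda2 = side$lambda2,
        fit = as.list(side$fit))
}

#' Score a completed inference run
#'
#' Reads the dataset and fitted matrices, applies the regulon filters
#' ([filterRegulons()] then [dropPoorTargets()]), computes activity scores,
#' the dissimilarity table and per-phenotype centralities, and writes one
#' activity TSV per phenotype plus \code{dissimilarity.tsv},
#' \code{centrality.tsv} and edge lists.
#'
#' @param dataDir run directory holding the dataset (see [runSimulate()]).
#' @param fitDir run directory holding the fitted matrices
#'   (see [runInference()]).
#' @param dir output directory.
#' @param nBins histogram resolution of the dissimilarity computation.
#' @return invisible list with \code{activity}, \code{dissimilarity},
#'   \code{centrality}.
#' @export
runScoring <- function(dataDir, fitDir, dir, nBins = 100L) {
    ds <- readRunDataset(dataDir)
    wset <- readIncidenceMatrices(fitDir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    filt <- filterRegulons(wset)
    r2path <- file.path(fitDir, "adjusted_r2.tsv")
    if (file.exists(r2path)) {
        r2 <- data.table::fread(r2path, data.table = FALSE)
        filt <- dropPoorTargets(rowMeans(as.matrix(r2[, -1L, drop = FALSE]),
                                         na.rm = TRUE),
                                filter = filt)
    }
    act <- activityMatrix(ds, wset, filt)
    for (lv in act@phenotypeOrder) {
        A <- activityScores(act, lv)
        data.table::fwrite(data.frame(cell_id = rownames(A), A,
                                      check.names = FALSE),
                           file.path(dir, sprintf("activity_%s.tsv", lv)),
                           sep = "\t")
    }
    dis <- dissimilarityTable(act, cellClusters(ds), nBins = nBins)
    data.table::fwrite(data.frame(driver = rownames(dis), dis,
                                  check.names = FALSE),
                       file.path(dir, "dissimilarity.tsv"), sep = "\t")
    cent <- do.call(rbind, lapply(seq_along(wset@phenotypeOrder), function(k) {
        lv <- wset@phenotypeOrder[k]
        g <- buildBipartiteGraph(incidenceMatrix(wset, lv), filt, state = k,
                                 phenotype = lv)
        writeEdgeList(g, file.path(dir, sprintf("edges_%s.tsv", lv)))
        if (igraph::ecount(g) == 0L) return(NULL)
        cbind(phenotype = lv, authorityHubScores(g))
    }))
    if (is.null(cent))
        cent <- data.frame(phenotype = character(), gene = character(),
                           role = character(), authority = numeric(),
                           hub = numeric())
    data.table::fwrite(cent, file.path(dir, "centrality.tsv"), sep = "\t")
    .writeConfig(list(subcommand = "score", dataDir = dataDir,
                      fitDir = fitDir, nBins = nBins), dir)
    invisible(list(activity = act, dissimilarity = dis, centrality = cent))
}

#' Evaluate a fitted run against the synthetic truth
#'
#' Reads fitted and true matrices from their run directories, thresholds
#' the weights and writes micro-F1 and Cohen's kappa per state
#' (\code{evaluation.tsv} and \code{evaluation.json}).
#'
#' @param fitDir directory from [runInference()].
#' @param truthDir directory from [runSimulate()] (holds
#'   \code{truth_state<k>.tsv}).
#' @param dir output directory.
#' @param thr ternary threshold (default 0.5).
#' @return the evaluation data.frame, invisibly.
#' @export
runEvaluate <- function(fitDir, truthDir, dir, thr = 0.5) {
    wset <- readIncidenceMatrices(fitDir)
    K <- length(wset@phenotypeOrder)
    nets <- lapply(seq_len(K), function(k) {
        df <- data.table::fread(file.path(truthDir,
                                          sprintf("truth_state%d.tsv", k)),
                                data.table = FALSE)
        W <- as.matrix(df[, -1L, drop = FALSE])
        rownames(W) <- df[[1L]]
        W
    })
    truth <- new("SyntheticTruth", networks = nets,
                 params = list(), seed = NA_integer_)
    if (!identical(dim(nets[[1L]]),
                   c(length(wset@driverGenes), length(wset@targetGenes))))
        stop("fitted and true matrices have mismatched shapes")
    res <- evaluateRecovery(wset, truth, thr)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(res, file.path(dir, "evaluation.tsv"), sep = "\t")
    jsonlite::write_json(res, file.path(dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeConfig(list(subcommand = "evaluate", fitDir = fitDir,
                      truthDir = truthDir, threshold = thr), dir)
    invisible(res)
}
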