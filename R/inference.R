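#' Solver configuration for the joint network fit
#'
#' @param maxEpochs cap on full passes over the K state blocks.
#' @param tol stop when the relative objective change between consecutive
#'   full passes falls below this value.
#' @param seed integer seed for the random block schedule.
#' @param schedule \code{"random"} (a uniformly random state block per step,
#'   the method as published) or \code{"cyclic"} (deterministic sweep
#'   1..K; the objective trace is non-increasing pass over pass).
#' @param penalizeBias apply the L1 and similarity penalties to the bias row
#'   too (the literal reading of folding the intercept into W). Off by
#'   default: penalising the intercept distorts the fit.
#' @return a list of class \code{"solverConfig"}.
#' @export
solverConfig <- function(maxEpochs = 1000L, tol = 1e-5, seed = 1L,
                         schedule = c("random", "cyclic"),
                         penalizeBias = FALSE) {
    stopifnot(maxEpochs >= 1L, tol > 0)
    structure(list(maxEpochs = as.integer(maxEpochs), tol = tol,
                   seed = as.integer(seed), schedule = match.arg(schedule),
                   penalizeBias = isTRUE(penalizeBias)),
              class = "solverConfig")
}

#' Elementwise soft-thresholding operator
#'
#' \code{sign(v) * max(|v| - t, 0)}, the proximal operator of the L1 penalty.
#'
#' @param v numeric vector or matrix.
#' @param t non-negative threshold.
#' @export
softThreshold <- function(v, t) {
    stopifnot(t >= 0)
    sign(v) * pmax(abs(v) - t, 0)
}

# Precompute per-state sufficient statistics on a cell subset.
# Returned Gram matrices make each solver pass O((m+1)^2 n) per state,
# independent of the number of cells.
.precomputeStates <- function(ds, cells = NULL) {
    ord <- phenotypeOrder(ds)
    drv <- driverGenes(ds)
    tgt <- targetGenes(ds)
    states <- lapply(ord, function(lv) {
        X <- driverMatrix(ds, lv, cells)
        Y <- targetMatrix(ds, lv, cells)
        if (nrow(X) < 1L) stop("phenotype '", lv, "' has no cells")
        Xb <- cbind(X, `(bias)` = 1)
        G <- crossprod(Xb)
        # curvature of the quadratic loss in one block
        lipQuad <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
        # gamma_k of the published algorithm (bias column excluded)
        gamma <- max(eigen(crossprod(X), symmetric = TRUE,
                           only.values = TRUE)$values)
        zeroVar <- apply(X, 2L, function(col) diff(range(col)) == 0)
        # centered statistics: with an unpenalized bias the intercept can be
        # profiled out exactly, which decouples it from the (large) driver
        # means and conditions the problem far better
        mx <- colMeans(X)
        my <- colMeans(Y)
        Xc <- sweep(X, 2L, mx)
        Yc <- sweep(Y, 2L, my)
        Gc <- crossprod(Xc)
        lipC <- max(eigen(Gc, symmetric = TRUE, only.values = TRUE)$values)
        list(G = G, C = crossprod(Xb, Y), yss = sum(Y^2), nCells = nrow(X),
             lipQuad = lipQuad, gamma = gamma, zeroVar = zeroVar,
             Gc = Gc, Cc = crossprod(Xc, Yc), yssc = sum(Yc^2),
             lipC = lipC, mx = mx, my = my)
    })
    names(states) <- ord
    list(states = states, drivers = drv, targets = tgt, order = ord)
}

# Objective of the joint problem on precomputed statistics. In centered
# mode W carries only driver rows and the loss is the bias-profiled one
# (exact partial minimisation over the unpenalized intercept).
.objectiveCore <- function(W, pre, lambda1, lambda2, penRows,
                           centered = FALSE) {
    K <- length(W)
    f <- 0
    for (k in seq_len(K)) {
        st <- pre$states[[k]]
        f <- f + if (centered) {
            0.5 * (st$yssc - 2 * sum(W[[k]] * st$Cc) +
                   sum(W[[k]] * (st$Gc %*% W[[k]])))
        } else {
            0.5 * (st$yss - 2 * sum(W[[k]] * st$C) +
                   sum(W[[k]] * (st$G %*% W[[k]])))
        }
        f <- f + lambda1 * sum(abs(W[[k]][penRows, , drop = FALSE]))
        if (k < K)
            f <- f + lambda2 *
                sum((W[[k]][penRows, , drop = FALSE] -
                     W[[k + 1L]][penRows, , drop = FALSE])^2)
    }
    f
}

.fitCore <- function(pre, lambda1, lambda2, config) {
    K <- length(pre$states)
    m <- length(pre$drivers)
    n <- length(pre$targets)
    centered <- !config$penalizeBias
    nr <- if (centered) m else m + 1L
    penRows <- seq_len(if (centered) m else m + 1L)
    dn <- list(if (centered) pre$drivers else c(pre$drivers, "(bias)"),
               pre$targets)
    W <- replicate(K, matrix(0, nr, n, dimnames = dn), simplify = FALSE)
    deg <- if (K == 1L) rep(0L, 1L) else
        ifelse(seq_len(K) %in% c(1L, K), 1L, 2L)
    # Block Lipschitz constant: quadratic-loss curvature plus the similarity
    # term's 2*lambda2 per chain neighbour. The literal step 1/gamma_k
    # diverges once lambda2 dominates; adding the coupling curvature keeps
    # every proximal block update a descent step.
    L <- vapply(seq_len(K), function(k) {
        lq <- if (centered) pre$states[[k]]$lipC else pre$states[[k]]$lipQuad
        max(lq, .Machine$double.eps) + 2 * lambda2 * deg[k]
    }, numeric(1))
    zeroVarWarned <- FALSE

    updateBlock <- function(k) {
        st <- pre$states[[k]]
        grad <- if (centered) st$Gc %*% W[[k]] - st$Cc
                else st$G %*% W[[k]] - st$C
        if (K > 1L) {
            d <- W[[k]][penRows, , drop = FALSE] * deg[k]
            if (k > 1L) d <- d - W[[k - 1L]][penRows, , drop = FALSE]
            if (k < K) d <- d - W[[k + 1L]][penRows, , drop = FALSE]
            grad[penRows, ] <- grad[penRows, , drop = FALSE] + 2 * lambda2 * d
        }
        Wk <- W[[k]] - grad / L[k]
        Wk[penRows, ] <- softThreshold(Wk[penRows, , drop = FALSE],
                                       lambda1 / L[k])
        if (any(st$zeroVar)) {
            if (!zeroVarWarned) {
                warning("zero-variance driver(s); their weights are pinned to 0")
                zeroVarWarned <<- TRUE
            }
            Wk[which(st$zeroVar), ] <- 0
        }
        W[[k]] <<- Wk
    }

    trace <- numeric(0)
    fPrev <- .objectiveCore(W, pre, lambda1, lambda2, penRows, centered)
    converged <- FALSE
    runEpochs <- function() {
        for (epoch in seq_len(config$maxEpochs)) {
            blocks <- if (config$schedule == "cyclic") seq_len(K)
                      else sample.int(K, K, replace = TRUE)
            for (k in blocks) updateBlock(k)
            f <- .objectiveCore(W, pre, lambda1, lambda2, penRows, centered)
            if (!is.finite(f))
                stop("objective diverged; increase the step denominator ",
                     "(gamma_k) or rescale the expression")
            trace[epoch] <<- f
            if (abs(fPrev - f) < config$tol * max(abs(fPrev), 1e-12)) {
                converged <<- TRUE
                fPrev <<- f
                break
            }
            fPrev <<- f
        }
    }
    if (config$schedule == "random") {
        withr::with_seed(config$seed, runEpochs())
    } else runEpochs()

    if (centered) {
        # recover the profiled intercept: b = mean(Y) - mean(X) %*% W
        W <- lapply(seq_len(K), function(k) {
            st <- pre$states[[k]]
            b <- st$my - as.numeric(st$mx %*% W[[k]])
            rbind(W[[k]], `(bias)` = b)
        })
    }
    list(W = W, trace = trace, converged = converged)
}

#' Jointly fit one regulatory network per ordered phenotype
#'
#' Minimises, over the K incidence matrices \eqn{W^k},
#' \deqn{\sum_k \tfrac12\|Y^k - X^k W^k\|_2^2 + \lambda_1 \sum_k |W^k|_1
#'       + \lambda_2 \sum_{k<K} \|W^k - W^{k+1}\|_2^2,}
#' where \eqn{X^k} (cells x drivers, plus a constant column for the bias) and
#' \eqn{Y^k} (cells x targets) hold the expression of the cells in phenotype
#' \eqn{k}. The problem is convex; it is solved by proximal block coordinate
#' descent: a selected state block takes a gradient step on the smooth part
#' (quadratic loss plus the similarity coupling to its chain neighbours) and
#' then soft-thresholds its non-bias entries. With \eqn{\lambda_2 = 0} the
#' states decouple into independent LASSO problems; as \eqn{\lambda_2}
#' grows the K matrices are driven towards a common consensus.
#'
#' @param ds a [GRNExperiment-class].
#' @param lambda1 L1 sparsity weight (>= 0).
#' @param lambda2 similarity weight (>= 0) along \code{phenotypeOrder(ds)}.
#' @param config a [solverConfig()].
#' @param split optional [splitTrainTest()] result: the model is then fitted
#'   on the training cells and held-out adjusted R-squared per target is
#'   reported on the test cells.
#' @return a list with elements \code{weights} (an
#'   [IncidenceMatrixSet-class]) and \code{report} (a [FitReport-class]).
#' @examples
#' truth <- generateGRNChain(K = 2, m = 4, n = 3, seed = 7)
#' ds <- simulateExpression(truth, cellsPerState = 60, seed = 7)
#' fit <- fitJointGRNs(ds, lambda1 = 1e-2, lambda2 = 1e-2)
#' incidenceMatrix(fit$weights, "state1")[1:3, ]
#' @export
fitJointGRNs <- function(ds, lambda1, lambda2, config = solverConfig(),
                         split = NULL) {
    stopifnot(is(ds, "GRNExperiment"), lambda1 >= 0, lambda2 >= 0)
    cells <- if (is.null(split)) NULL else trainCells(split)
    pre <- .precomputeStates(ds, cells)
    sol <- .fitCore(pre, lambda1, lambda2, config)
    wset <- new("IncidenceMatrixSet", weights = sol$W,
                driverGenes = pre$drivers, targetGenes = pre$targets,
                phenotypeOrder = pre$order, lambda1 = lambda1,
                lambda2 = lambda2,
                fit = list(converged = sol$converged,
                           epochs = length(sol$trace),
                           objective = unname(utils::tail(sol$trace, 1L)),
                           schedule = config$schedule, seed = config$seed))
    r2 <- matrix(NA_real_, length(pre$targets), length(pre$order),
                 dimnames = list(pre$targets, pre$order))
    if (!is.null(split)) r2 <- goodnessOfFit(ds, wset, testCells(split))
    nnz <- rowSums(vapply(sol$W, function(Wk)
        colSums(abs(Wk[seq_along(pre$drivers), , drop = FALSE]) > 1e-8),
        numeric(length(pre$targets))))
    report <- new("FitReport", objectiveTrace = sol$trace, adjustedR2 = r2,
                  medianAdjustedR2 = stats::median(r2, na.rm = TRUE),
                  driversPerTarget = as.integer(round(nnz /
                      length(pre$order))))
    list(weights = wset, report = report)
}

#' @rdname IncidenceMatrixSet-accessors
#' @export
setMethod("incidenceMatrix", "IncidenceMatrixSet",
    function(x, phenotype, withBias = TRUE) {
        k <- match(phenotype, x@phenotypeOrder)
        if (is.na(k)) stop("unknown phenotype: ", phenotype)
        W <- x@weights[[k]]
        if (!withBias) W <- W[seq_along(x@driverGenes), , drop = FALSE]
        W
    })

#' @export
setMethod("length", "IncidenceMatrixSet", function(x) length(x@weights))

#' @export
setMethod("show", "IncidenceMatrixSet", function(object) {
    cat("IncidenceMatrixSet: ", length(object@driverGenes), " drivers x ",
        length(object@targetGenes), " targets x ",
        length(object@phenotypeOrder), " phenotypes\n", sep = "")
    cat("lambda1 =", object@lambda1, " lambda2 =", object@lambda2, "\n")
    if (length(object@fit))
        cat("solver: ", object@fit$schedule, ", ", object@fit$epochs,
            " epochs, converged = ", object@fit$converged, "\n", sep = "")
})

#' Joint objective value
#'
#' Evaluates the fused-LASSO objective minimised by [fitJointGRNs()] at the
#' given weights. The bias row is excluded from both penalty terms unless
#' \code{penalizeBias}.
#'
#' @param wset an [IncidenceMatrixSet-class].
#' @param ds the matching [GRNExperiment-class].
#' @param lambda1,lambda2 penalty weights.
#' @param cells optional cell subset.
#' @param penalizeBias include the bias row in the penalties.
#' @return finite non-negative scalar.
#' @export
jointObjective <- function(wset, ds, lambda1 = wset@lambda1,
                           lambda2 = wset@lambda2, cells = NULL,
                           penalizeBias = FALSE) {
    if (!identical(wset@driverGenes, driverGenes(ds)) ||
        !identical(wset@targetGenes, targetGenes(ds)) ||
        !identical(wset@phenotypeOrder, phenotypeOrder(ds)))
        stop("weights and dataset do not share gene/phenotype indexing")
    pre <- .precomputeStates(ds, cells)
    m <- length(wset@driverGenes)
    penRows <- if (penalizeBias) seq_len(m + 1L) else seq_len(m)
    .objectiveCore(wset@weights, pre, lambda1, lambda2, penRows)
}

#' Predict target expression from driver expression
#'
#' The linear regulation model: predicted targets are \code{cbind(X, 1) \%*\% W}
#' with the incidence matrix's trailing bias row as intercept.
#'
#' @param W an (m+1) x n incidence matrix (bias row last) or m x n matrix
#'   without bias.
#' @param X cells x drivers expression.
#' @return cells x targets predicted expression.
#' @export
predictTargets <- function(W, X) {
    X <- as.matrix(X)
    if (nrow(W) == ncol(X) + 1L) X <- cbind(X, 1)
    if (nrow(W) != ncol(X)) stop("shape mismatch between W and X")
    X %*% W
}

#' Adjusted R-squared
#'
#' \eqn{1 - (1 - R^2)(n - 1)/(n - p - 1)} with
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}; may be negative. A zero-variance
#' \code{yTrue} makes the quantity undefined and returns \code{NA}.
#'
#' @param yTrue,yPred numeric vectors of equal length (>= p + 2).
#' @param p number of predictors.
#' @export
adjustedR2 <- function(yTrue, yPred, p) {
    n <- length(yTrue)
    stopifnot(length(yPred) == n, n >= p + 2L)
    sst <- sum((yTrue - mean(yTrue))^2)
    if (sst == 0) return(NA_real_)
    r2 <- 1 - sum((yTrue - yPred)^2) / sst
    1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Held-out goodness of fit per target and phenotype
#'
#' Predicts each state's target expression on the given cells from the
#' fitted incidence matrix and reports the adjusted R-squared per target,
#' with the full driver count as the number of predictors.
#'
#' @param ds a [GRNExperiment-class].
#' @param wset an [IncidenceMatrixSet-class].
#' @param cells cell ids to evaluate on (e.g. [testCells()]).
#' @return targets x phenotypes numeric matrix.
#' @export
goodnessOfFit <- function(ds, wset, cells) {
    m <- length(wset@driverGenes)
    ord <- wset@phenotypeOrder
    out <- matrix(NA_real_, length(wset@targetGenes), length(ord),
                  dimnames = list(wset@targetGenes, ord))
    for (lv in ord) {
        X <- driverMatrix(ds, lv, cells)
        if (nrow(X) < m + 2L) next
        Y <- targetMatrix(ds, lv, cells)
        P <- predictTargets(incidenceMatrix(wset, lv), X)
        out[, lv] <- vapply(seq_len(ncol(Y)), function(j)
            adjustedR2(Y[, j], P[, j], m), numeric(1))
    }
    out
}

#' @export
setMethod("show", "FitReport", function(object) {
    cat("FitReport: ", length(object@objectiveTrace), " epochs, final objective ",
        format(utils::tail(object@objectiveTrace, 1L)), "\n", sep = "")
    cat("median held-out adjusted R^2: ",
        format(object@medianAdjustedR2), "\n", sep = "")
})
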