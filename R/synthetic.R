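#' Generate a ternary ground-truth network chain
#'
#' Builds K drivers x targets incidence matrices with entries in
#' \{-1, 0, +1\}. The first state is drawn i.i.d. per edge (+1 with
#' probability \code{pPlus}, -1 with \code{pMinus}, 0 otherwise). Each later
#' state modifies the previous one edgewise: a non-zero edge flips sign with
#' probability \code{pFlip}, is zeroed with probability \code{pToZero}, and
#' keeps its value otherwise; a zero edge stays zero with probability
#' \code{pKeepZero} and becomes +1 or -1 with equal probability otherwise.
#' Note that at the default rates \code{pFlip + pToZero = 1}: a non-zero
#' edge never survives unchanged, and the non-zero density drifts from
#' \code{pPlus + pMinus} towards its stationary value along the chain.
#'
#' @param K number of states (default 5).
#' @param m drivers (default 50), n targets (default 20).
#' @param n number of targets.
#' @param pPlus,pMinus first-state edge probabilities (defaults 0.1/0.1).
#' @param pFlip,pToZero,pKeepZero transition rates (defaults 0.3, 0.7, 0.5).
#' @param negbin length-2 vector (size, prob) of the TF expression model.
#' @param noiseSd standard deviation of the Gaussian noise added to targets.
#' @param seed integer seed.
#' @return a [SyntheticTruth-class].
#' @export
generateGRNChain <- function(K = 5L, m = 50L, n = 20L,
                             pPlus = 0.1, pMinus = 0.1,
                             pFlip = 0.3, pToZero = 0.7, pKeepZero = 0.5,
                             negbin = c(size = 5, prob = 0.5),
                             noiseSd = 4, seed = 1L) {
    probs <- c(pPlus, pMinus, pFlip, pToZero, pKeepZero)
    if (any(probs < 0 | probs > 1) || pPlus + pMinus > 1 ||
        pFlip + pToZero > 1)
        stop("invalid probabilities")
    dn <- list(paste0("TF", seq_len(m)), paste0("TG", seq_len(n)))
    nets <- withr::with_seed(as.integer(seed), {
        out <- vector("list", K)
        out[[1L]] <- matrix(sample(c(1, -1, 0), m * n, replace = TRUE,
                                   prob = c(pPlus, pMinus, 1 - pPlus - pMinus)),
                            m, n, dimnames = dn)
        for (k in seq_len(K - 1L) + 1L) {
            prev <- out[[k - 1L]]
            u <- matrix(stats::runif(m * n), m, n)
            cur <- prev
            nz <- prev != 0
            cur[nz] <- ifelse(u[nz] < pFlip, -prev[nz],
                              ifelse(u[nz] < pFlip + pToZero, 0, prev[nz]))
            z <- !nz
            s <- matrix(sample(c(1, -1), m * n, replace = TRUE), m, n)
            cur[z] <- ifelse(u[z] < pKeepZero, 0, s[z])
            dimnames(cur) <- dn
            out[[k]] <- cur
        }
        out
    })
    new("SyntheticTruth", networks = nets,
        params = list(edgeProbs = c(plus = pPlus, minus = pMinus,
                                    zero = 1 - pPlus - pMinus),
                      transitionProbs = c(flip = pFlip, toZero = pToZero,
                                          keepNonzero = 1 - pFlip - pToZero,
                                          keepZero = pKeepZero,
                                          toNonzero = (1 - pKeepZero) / 2),
                      negbin = negbin, noiseSd = noiseSd),
        seed = as.integer(seed))
}

#' @rdname SyntheticTruth-accessors
#' @export
setMethod("trueNetwork", "SyntheticTruth", function(x, state)
    x@networks[[state]])

#' @export
setMethod("length", "SyntheticTruth", function(x) length(x@networks))

#' @export
setMethod("show", "SyntheticTruth", function(object) {
    d <- dim(object@networks[[1L]])
    cat("SyntheticTruth: ", length(object@networks), " states, ",
        d[1L], " drivers x ", d[2L], " targets (seed ", object@seed, ")\n",
        sep = "")
    cat("nonzero density per state: ",
        paste(vapply(object@networks, function(W)
            sprintf("%.2f", mean(W != 0)), character(1)), collapse = " "),
        "\n", sep = "")
})

#' Simulate single-cell expression from a ground-truth chain
#'
#' TF expression is drawn i.i.d. from a negative binomial (number-of-failures
#' parameterisation; the defaults size = 5, prob = 0.5 give mean 5) and each
#' target is the linear combination of the TFs through the state's true
#' network plus i.i.d. Gaussian noise with sd \code{noiseSd}. Phenotype
#' labels are \code{"state1" ... "stateK"} in chain order.
#'
#' @param truth a [SyntheticTruth-class].
#' @param cellsPerState cells per state (default 1000).
#' @param seed integer seed.
#' @return a [GRNExperiment-class] with the TFs as drivers.
#' @export
simulateExpression <- function(truth, cellsPerState = 1000L, seed = 1L) {
    stopifnot(cellsPerState >= 1L)
    K <- length(truth@networks)
    m <- nrow(truth@networks[[1L]])
    n <- ncol(truth@networks[[1L]])
    nb <- truth@params$negbin
    sdN <- truth@params$noiseSd
    states <- paste0("state", seq_len(K))
    expr <- withr::with_seed(as.integer(seed), {
        lapply(seq_len(K), function(k) {
            X <- matrix(stats::rnbinom(cellsPerState * m, size = nb[[1L]],
                                       prob = nb[[2L]]),
                        cellsPerState, m)
            Y <- X %*% truth@networks[[k]] +
                matrix(stats::rnorm(cellsPerState * n, sd = sdN),
                       cellsPerState, n)
            rbind(t(X), t(Y))
        })
    })
    mat <- do.call(cbind, expr)
    rownames(mat) <- c(rownames(truth@networks[[1L]]),
                       colnames(truth@networks[[1L]]))
    colnames(mat) <- paste0(rep(states, each = cellsPerState), "_cell",
                            rep(seq_len(cellsPerState), K))
    GRNExperiment(mat,
                  phenotype = rep(states, each = cellsPerState),
                  phenotypeOrder = states,
                  drivers = rownames(truth@networks[[1L]]))
}

#' Threshold real-valued weights into ternary edge classes
#'
#' Weights above \code{thr} map to +1, below \code{-thr} to -1, the rest to
#' 0. The inequalities are strict: a weight of exactly \code{thr} maps to 0.
#'
#' @param W numeric matrix.
#' @param thr positive threshold (default 0.5).
#' @return matrix with entries in \{-1, 0, +1\}.
#' @export
thresholdWeights <- function(W, thr = 0.5) {
    stopifnot(thr > 0)
    (W > thr) - (W < -thr)
}

.confusion <- function(truth, pred, classes = c(-1, 0, 1)) {
    if (!identical(dim(as.matrix(truth)), dim(as.matrix(pred))))
        stop("shape mismatch")
    t <- factor(as.vector(as.matrix(truth)), levels = classes)
    p <- factor(as.vector(as.matrix(pred)), levels = classes)
    table(truth = t, pred = p)
}

#' Micro-averaged F1 of ternary edge recovery
#'
#' Aggregates true/false positives and negatives over the three edge
#' classes \{-1, 0, +1\} before forming the F1 score. In this single-label
#' multi-class setting micro-F1 equals accuracy, so an all-zero prediction
#' on a sparse truth already scores the truth's zero fraction — the reason
#' Cohen's kappa is reported alongside.
#'
#' @param truth,pred ternary matrices of identical shape.
#' @return value in [0, 1].
#' @export
microF1 <- function(truth, pred) {
    cm <- .confusion(truth, pred)
    tp <- sum(diag(cm))
    fp <- sum(colSums(cm) - diag(cm))
    fn <- sum(rowSums(cm) - diag(cm))
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    if (prec + rec == 0) return(0)
    2 * prec * rec / (prec + rec)
}

#' Cohen's kappa of ternary edge recovery
#'
#' Chance-corrected agreement \eqn{(p_o - p_e)/(1 - p_e)} with expected
#' agreement \eqn{p_e} from the class marginals. When \eqn{p_e = 1}
#' (degenerate single-class marginals) the value is 1 if the observed
#' agreement is also perfect and 0 otherwise.
#'
#' @param truth,pred ternary matrices of identical shape.
#' @return value in [-1, 1].
#' @export
cohensKappa <- function(truth, pred) {
    cm <- .confusion(truth, pred)
    N <- sum(cm)
    po <- sum(diag(cm)) / N
    pe <- sum(rowSums(cm) * colSums(cm)) / N^2
    if (1 - pe < .Machine$double.eps) return(if (po == 1) 1 else 0)
    (po - pe) / (1 - pe)
}

#' Cluster activity scores and compare against known labels
#'
#' k-means (10 restarts, seeded) on a cells x drivers activity matrix,
#' evaluated against the true cell labels with the adjusted Rand index.
#'
#' @param scores cells x drivers numeric matrix (NA columns are dropped).
#' @param trueLabels per-cell labels (length = rows of \code{scores}).
#' @param k number of clusters (>= 2).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return ARI in [-1, 1].
#' @export
clusteringARI <- function(scores, trueLabels, k, seed = 1L, nstart = 10L) {
    stopifnot(k >= 2L, nrow(scores) == length(trueLabels))
    if (k > nrow(scores)) stop("more clusters than cells")
    keep <- colSums(is.na(scores)) == 0L
    km <- withr::with_seed(as.integer(seed),
        stats::kmeans(scores[, keep, drop = FALSE], centers = k,
                      nstart = nstart))
    mclust::adjustedRandIndex(km$cluster, trueLabels)
}

#' Evaluate inferred networks against the synthetic truth
#'
#' Thresholds each state's inferred weights into ternary classes and reports
#' micro-F1 and Cohen's kappa per state.
#'
#' @param wset an [IncidenceMatrixSet-class] (bias row ignored).
#' @param truth a [SyntheticTruth-class] of matching shape.
#' @param thr threshold passed to [thresholdWeights()].
#' @return data.frame with one row per state: \code{state}, \code{microF1},
#'   \code{kappa}, \code{threshold}.
#' @export
evaluateRecovery <- function(wset, truth, thr = 0.5) {
    K <- length(truth@networks)
    if (length(wset@weights) != K) stop("state count mismatch")
    m <- length(wset@driverGenes)
    do.call(rbind, lapply(seq_len(K), function(k) {
        Wd <- wset@weights[[k]][seq_len(m), , drop = FALSE]
        pred <- thresholdWeights(Wd, thr)
        data.frame(state = wset@phenotypeOrder[k],
                   microF1 = microF1(truth@networks[[k]], pred),
                   kappa = cohensKappa(truth@networks[[k]], pred),
                   threshold = thr)
    }))
}
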