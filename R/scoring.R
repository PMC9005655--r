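#' Normalize incidence weights by target expression norms
#'
#' Edge weights are comparable across drivers for a fixed target but not
#' across targets, since target expression scales differ. Dividing column j
#' by the Euclidean norm of target j's expression (over the cells of the
#' state at hand) puts regulon weights on a common scale before activity
#' scoring. Zero-norm targets get a zero column, with a warning.
#'
#' @param W incidence matrix, (m+1) x n with trailing bias row or m x n;
#'   the bias row is dropped.
#' @param Y cells x targets expression of the same state; columns must match
#'   the columns of \code{W}.
#' @param norm \code{"euclidean"} (default) or \code{"l1"}.
#' @return an m x n matrix of normalized weights.
#' @export
normalizeWeights <- function(W, Y, norm = c("euclidean", "l1")) {
    norm <- match.arg(norm)
    Y <- as.matrix(Y)
    if (ncol(W) != ncol(Y)) stop("W and Y must share target columns")
    if (!is.null(rownames(W)) && rownames(W)[nrow(W)] == "(bias)")
        W <- W[-nrow(W), , drop = FALSE]
    nrm <- if (norm == "euclidean") sqrt(colSums(Y^2)) else colSums(abs(Y))
    if (any(nrm == 0)) {
        warning("zero-norm target expression; column(s) set to 0")
        nrm[nrm == 0] <- Inf
    }
    sweep(W, 2L, nrm, "/")
}

#' Per-cell activity score of one weighted regulon
#'
#' The supplied weight vector is the driver's regulon over T target genes
#' (zero-weight entries carry no mass but still occupy rank positions; at
#' least one weight must be non-zero). For a given cell the T weights are
#' ordered by the cell's target expression and accumulated; the score is the
#' normalized area under the cumulative-sum curve,
#' \deqn{\frac{\sum_{t=1}^{T} \sum_{u \le t} \hat W_{i,u}/T}
#'            {\sum_{t=1}^{T} \hat W_{i,t}} \in [0, 1].}
#' By default targets are ranked by DESCENDING expression, so the score
#' approaches 1 when the strongly weighted targets are the highly expressed
#' ones, and 1/T when they are the least expressed. Weight magnitudes are
#' used for ordering and accumulation (the formula's [0,1] range fails for
#' signed weights); edge signs are reported in the network outputs instead.
#' Ties in expression are broken by gene index.
#'
#' @param cellExpr numeric vector of the cell's target expression.
#' @param weights normalized regulon weight vector (same length/order).
#' @param ascending rank by ascending expression instead.
#' @param signed accumulate signed weights as-is (range no longer [0,1]).
#' @return scalar score, or \code{NA} for an empty regulon.
#' @examples
#' activityScore(c(3, 2, 1), c(0.2, 0.2, 0.2))  # equal weights: (T+1)/(2T)
#' @export
activityScore <- function(cellExpr, weights, ascending = FALSE,
                          signed = FALSE) {
    stopifnot(length(cellExpr) == length(weights))
    w <- if (signed) weights else abs(weights)
    Tn <- length(w)
    if (all(w == 0)) return(NA_real_)
    r <- rank(if (ascending) cellExpr else -cellExpr, ties.method = "first")
    sum(w * (Tn + 1 - r)) / (Tn * sum(w))
}

#' Activity score matrices for all phenotypes
#'
#' Computes one cells x drivers activity matrix per phenotype, using only
#' that state's cells and incidence matrix: weights are normalized against
#' the state's target expression ([normalizeWeights()]), optionally masked
#' by a [filterRegulons()] result, and scored per cell with
#' [activityScore()].
#'
#' @param ds a [GRNExperiment-class].
#' @param wset a fitted [IncidenceMatrixSet-class].
#' @param filter optional [RegulonFilter-class]; filtered-out driver weights
#'   are zeroed and dropped targets excluded before scoring.
#' @param ascending,signed passed to [activityScore()].
#' @return an [ActivityScoreSet-class].
#' @export
activityMatrix <- function(ds, wset, filter = NULL, ascending = FALSE,
                           signed = FALSE) {
    ord <- wset@phenotypeOrder
    drv <- wset@driverGenes
    tgt <- wset@targetGenes
    scores <- stats::setNames(vector("list", length(ord)), ord)
    for (k in seq_along(ord)) {
        Y <- targetMatrix(ds, ord[k])
        if (nrow(Y) == 0L) stop("phenotype '", ord[k], "' has no cells")
        Wn <- normalizeWeights(incidenceMatrix(wset, ord[k]), Y)
        keepT <- rep(TRUE, length(tgt))
        if (!is.null(filter)) {
            Wn[!filter@keepDrivers[[k]]] <- 0
            keepT <- filter@keepTargets
        }
        A <- matrix(NA_real_, nrow(Y), length(drv),
                    dimnames = list(rownames(Y), drv))
        Tn <- sum(keepT)
        if (Tn > 0L) {
            # rank positions by (descending) expression, shared across
            # drivers: the regulon spans all retained targets
            if (Tn == 1L) {
                R <- matrix(1, nrow(Y), 1L)
            } else {
                E <- Y[, keepT, drop = FALSE]
                if (!ascending) E <- -E
                R <- t(apply(E, 1L, rank, ties.method = "first"))
            }
            for (i in seq_along(drv)) {
                w <- if (signed) Wn[i, keepT] else abs(Wn[i, keepT])
                if (all(w == 0)) next  # empty regulon sentinel
                A[, i] <- as.numeric(((Tn + 1) - R) %*% w) / (Tn * sum(w))
            }
        }
        scores[[k]] <- A
    }
    new("ActivityScoreSet", scores = scores, phenotypeOrder = ord)
}

#' @rdname ActivityScoreSet-accessors
#' @export
setMethod("activityScores", "ActivityScoreSet", function(x, phenotype) {
    k <- match(phenotype, x@phenotypeOrder)
    if (is.na(k)) stop("unknown phenotype: ", phenotype)
    x@scores[[k]]
})

#' @export
setMethod("show", "ActivityScoreSet", function(object) {
    cat("ActivityScoreSet over ", length(object@phenotypeOrder),
        " phenotypes\n", sep = "")
    for (k in seq_along(object@scores))
        cat("  ", object@phenotypeOrder[k], ": ",
            nrow(object@scores[[k]]), " cells x ",
            ncol(object@scores[[k]]), " drivers\n", sep = "")
})

#' Keep the smallest driver set explaining most of each target's weight mass
#'
#' For every target, drivers are sorted by decreasing squared weight and the
#' shortest prefix whose cumulative squared-weight share reaches
#' \code{varianceFraction} (default 90\%) is retained; the remaining small
#' weights are treated as numerical noise of the optimisation. Applied per
#' phenotype.
#'
#' @param wset an [IncidenceMatrixSet-class].
#' @param varianceFraction cumulative share in (0, 1].
#' @return a [RegulonFilter-class] (with all targets kept; combine with
#'   [dropPoorTargets()] for the goodness-of-fit rule).
#' @export
filterRegulons <- function(wset, varianceFraction = 0.9) {
    stopifnot(varianceFraction > 0, varianceFraction <= 1)
    m <- length(wset@driverGenes)
    keep <- lapply(wset@weights, function(Wk) {
        Wd <- Wk[seq_len(m), , drop = FALSE]
        mask <- matrix(FALSE, m, ncol(Wd), dimnames = dimnames(Wd))
        for (j in seq_len(ncol(Wd))) {
            w2 <- Wd[, j]^2
            tot <- sum(w2)
            if (tot == 0) next  # empty driver set; target flagged downstream
            o <- order(-w2)
            s <- cumsum(w2[o]) / tot
            nkeep <- which(s >= varianceFraction)[1L]
            mask[o[seq_len(nkeep)], j] <- TRUE
        }
        mask
    })
    new("RegulonFilter", keepDrivers = keep,
        keepTargets = rep(TRUE, length(wset@targetGenes)),
        varianceFraction = varianceFraction)
}

#' Drop targets with a poor held-out fit
#'
#' Targets whose held-out adjusted R-squared falls below \code{threshold}
#' (default 0.7) are considered unexplained by the driver set and excluded
#' from downstream scoring, guarding against false-positive regulons.
#'
#' @param report a [FitReport-class], or a numeric vector/matrix of per-target
#'   adjusted R-squared (matrices are averaged across phenotypes).
#' @param threshold keep targets with adjusted R-squared >= this value.
#' @param filter optional [RegulonFilter-class] to update in place.
#' @return logical mask over targets, or the updated filter when one is given.
#' @export
dropPoorTargets <- function(report, threshold = 0.7, filter = NULL) {
    r2 <- if (is(report, "FitReport")) report@adjustedR2 else report
    if (is.matrix(r2)) r2 <- rowMeans(r2, na.rm = TRUE)
    mask <- !is.na(r2) & r2 >= threshold
    if (!any(mask)) warning("no target reaches the goodness-of-fit threshold")
    if (is.null(filter)) return(mask)
    filter@keepTargets <- unname(mask)
    filter
}

#' Bin activity scores into a distribution on [0, 1]
#'
#' Equal-width histogram making the countable sample space of the total
#' variation distance concrete for continuous scores: bins are
#' left-closed/right-open except the last, which is closed at 1. \code{NA}
#' scores (empty-regulon sentinels) are dropped.
#'
#' @param scores numeric vector of scores in [0, 1].
#' @param nBins number of bins (default 100).
#' @param label optional population descriptor.
#' @return a [ScoreDistribution-class].
#' @export
scoreDistribution <- function(scores, nBins = 100L, label = "") {
    scores <- scores[!is.na(scores)]
    if (!length(scores)) stop("no scores to bin")
    if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
    idx <- pmin(floor(scores * nBins) + 1L, nBins)
    counts <- tabulate(idx, nBins)
    new("ScoreDistribution", edges = seq(0, 1, length.out = nBins + 1L),
        prob = counts / sum(counts), label = as.character(label))
}

#' Total variation distance between two binned distributions
#'
#' \eqn{\delta(P, Q) = \tfrac12 \sum_\omega |P(\omega) - Q(\omega)|}.
#'
#' @param P,Q [ScoreDistribution-class] objects on identical bins.
#' @return value in [0, 1].
#' @export
totalVariation <- function(P, Q) {
    if (!isTRUE(all.equal(P@edges, Q@edges)))
        stop("distributions are binned differently")
    0.5 * sum(abs(P@prob - Q@prob))
}

#' Minmax total variation of K distributions
#'
#' \deqn{\delta_{minmax}(\{P_1,\dots,P_K\}) = \frac1K \sum_\omega
#'       \big(\max_i P_i(\omega) - \min_j P_j(\omega)\big),}
#' a multi-distribution generalisation of the total variation distance: 0
#' for identical distributions, 1 for mutually disjoint supports, and equal
#' to [totalVariation()] when K = 2.
#'
#' @param dists list of >= 2 [ScoreDistribution-class] objects, shared bins.
#' @return value in [0, 1].
#' @export
minmaxTV <- function(dists) {
    if (length(dists) < 2L) stop("at least two distributions are required")
    edges <- dists[[1L]]@edges
    for (d in dists)
        if (!isTRUE(all.equal(d@edges, edges)))
            stop("distributions are binned differently")
    P <- vapply(dists, slot, numeric(length(edges) - 1L), "prob")
    sum(apply(P, 1L, max) - apply(P, 1L, min)) / length(dists)
}

#' Regulatory dissimilarity of every regulon across phenotypes, per cluster
#'
#' For each driver and each cell cluster, builds one activity-score
#' distribution per phenotype from the cluster's cells and summarises their
#' divergence with [minmaxTV()]: values near 0 mean the regulon's activity
#' is unchanged across states, values near 1 that it shifted entirely. A
#' cluster with no scored cells in some phenotype yields \code{NA} (with a
#' warning), never a fabricated 0.
#'
#' @param act an [ActivityScoreSet-class] (row names are cell ids).
#' @param clusters named character vector mapping cell id to cluster, or
#'   \code{NULL} for a single pseudo-cluster \code{"all"}.
#' @param nBins histogram resolution, as in [scoreDistribution()].
#' @return drivers x clusters numeric matrix with values in [0, 1].
#' @export
dissimilarityTable <- function(act, clusters = NULL, nBins = 100L) {
    if (length(act@phenotypeOrder) < 2L)
        stop("dissimilarity requires at least two phenotypes")
    drv <- colnames(act@scores[[1L]])
    allCells <- unlist(lapply(act@scores, rownames), use.names = FALSE)
    if (is.null(clusters))
        clusters <- stats::setNames(rep("all", length(allCells)), allCells)
    cls <- sort(unique(clusters[allCells]))
    out <- matrix(NA_real_, length(drv), length(cls),
                  dimnames = list(drv, cls))
    warned <- FALSE
    for (g in cls) {
        perState <- lapply(act@scores, function(A)
            A[rownames(A) %in% names(clusters)[clusters == g], , drop = FALSE])
        for (i in seq_along(drv)) {
            sc <- lapply(perState, function(A) A[, i][!is.na(A[, i])])
            if (any(!vapply(sc, length, integer(1)))) {
                if (!warned) {
                    warning("cluster empty (or unscored) in some phenotype; ",
                            "entries left missing")
                    warned <- TRUE
                }
                next
            }
            out[i, g] <- minmaxTV(lapply(sc, scoreDistribution, nBins = nBins))
        }
    }
    out
}
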