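#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata "metadata<-" DataFrame
NULL

#' GRNExperiment: imputed expression with phenotype ordering and a gene partition
#'
#' A \linkS4class{SummarizedExperiment} (genes in rows, cells in columns) whose
#' rows are partitioned into driver genes (transcription factors, used as
#' predictors) and target genes, and whose cells carry a phenotype label drawn
#' from a user-supplied linear ordering of cell states. The expression assay is
#' assumed already imputed (no missing values); the package performs no
#' normalisation of its own.
#'
#' Row metadata must contain a \code{role} column with values \code{"driver"}
#' or \code{"target"}; column metadata must contain \code{phenotype} and may
#' contain \code{cluster}; \code{metadata(x)$phenotypeOrder} stores the state
#' ordering along which the fused similarity penalty couples consecutive
#' networks.
#'
#' @seealso [GRNExperiment()], [readGRNExperiment()], [fitJointGRNs()]
#' @export
setClass("GRNExperiment", contains = "SummarizedExperiment")

setValidity("GRNExperiment", function(object) {
    msg <- character()
    if (!"expression" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expression' is required")
    else if (anyNA(SummarizedExperiment::assay(object, "expression")))
        msg <- c(msg, "expression matrix has missing entries (input must be imputed)")
    rd <- rowData(object)
    if (!"role" %in% colnames(rd)) {
        msg <- c(msg, "rowData must contain a 'role' column")
    } else {
        if (!all(rd$role %in% c("driver", "target")))
            msg <- c(msg, "gene roles must be 'driver' or 'target'")
        if (sum(rd$role == "driver") < 1L)
            msg <- c(msg, "at least one driver gene is required")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate cell ids")
    cd <- colData(object)
    ord <- metadata(object)$phenotypeOrder
    if (!"phenotype" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'phenotype' column")
    } else if (is.null(ord) || length(ord) < 1L) {
        msg <- c(msg, "metadata(x)$phenotypeOrder must list at least one phenotype")
    } else {
        if (anyDuplicated(ord))
            msg <- c(msg, "phenotypeOrder has duplicate labels")
        unknown <- setdiff(unique(cd$phenotype), ord)
        if (length(unknown))
            msg <- c(msg, paste0("phenotype label(s) not in phenotypeOrder: ",
                                 paste(unknown, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' IncidenceMatrixSet: one fitted incidence matrix per ordered phenotype
#'
#' Holds K weighted (drivers + bias) x targets incidence matrices sharing
#' gene indices, one per phenotype in the state ordering, together with the
#' penalty weights used to fit them. The last row of each matrix, named
#' \code{"(bias)"}, is the intercept of the linear regulation model and is
#' exempt from both penalties by default.
#'
#' @slot weights list of K numeric matrices, each (m+1) x n.
#' @slot driverGenes,targetGenes character vectors of gene ids (lengths m, n).
#' @slot phenotypeOrder character vector of length K.
#' @slot lambda1 L1 sparsity weight.
#' @slot lambda2 fused similarity weight coupling consecutive states.
#' @slot fit list with solver diagnostics (objective trace, epochs, convergence).
#' @export
setClass("IncidenceMatrixSet",
    representation(weights = "list", driverGenes = "character",
                   targetGenes = "character", phenotypeOrder = "character",
                   lambda1 = "numeric", lambda2 = "numeric", fit = "list"))

setValidity("IncidenceMatrixSet", function(object) {
    msg <- character()
    K <- length(object@phenotypeOrder)
    m <- length(object@driverGenes)
    n <- length(object@targetGenes)
    if (length(object@weights) != K)
        msg <- c(msg, "one weight matrix per phenotype is required")
    for (W in object@weights) {
        if (!is.matrix(W) || nrow(W) != m + 1L || ncol(W) != n) {
            msg <- c(msg, "all weight matrices must be (drivers+1) x targets")
            break
        }
        if (any(!is.finite(W))) { msg <- c(msg, "non-finite weights"); break }
    }
    if (length(msg)) msg else TRUE
})

#' TrainTestSplit: phenotype-stratified cell partition
#'
#' @slot train,test named lists (one element per phenotype) of cell ids.
#' @slot ratio training fraction.
#' @slot seed integer seed that produced the split.
#' @export
setClass("TrainTestSplit",
    representation(train = "list", test = "list", ratio = "numeric",
                   seed = "integer"))

#' ActivityScoreSet: per-cell weighted regulon activity
#'
#' One cells x drivers matrix per phenotype; every defined entry lies in
#' [0, 1]. Drivers with an empty regulon (no retained non-zero weight) carry
#' \code{NA}.
#' @slot scores named list of K numeric matrices (cells of that state x drivers).
#' @slot phenotypeOrder character vector of length K.
#' @export
setClass("ActivityScoreSet",
    representation(scores = "list", phenotypeOrder = "character"))

setValidity("ActivityScoreSet", function(object) {
    for (A in object@scores) {
        v <- A[is.finite(A)]
        if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
            return("activity scores must lie in [0, 1]")
    }
    TRUE
})

#' RegulonFilter: retained drivers per target and retained targets
#'
#' @slot keepDrivers list (one logical m x n matrix per phenotype): which
#'   driver weights are retained for each target after the cumulative
#'   squared-weight rule.
#' @slot keepTargets logical vector over targets (adjusted-R-squared rule).
#' @slot varianceFraction the cumulative fraction used.
#' @export
setClass("RegulonFilter",
    representation(keepDrivers = "list", keepTargets = "logical",
                   varianceFraction = "numeric"))

#' ScoreDistribution: binned distribution of activity scores on [0, 1]
#'
#' @slot edges bin edges (length bins + 1), equal width over [0, 1].
#' @slot prob per-bin probabilities summing to 1.
#' @slot label population descriptor (phenotype and/or cluster).
#' @export
setClass("ScoreDistribution",
    representation(edges = "numeric", prob = "numeric", label = "character"))

setValidity("ScoreDistribution", function(object) {
    if (length(object@prob) != length(object@edges) - 1L)
        return("probabilities and edges are inconsistent")
    if (any(object@prob < 0)) return("negative bin probability")
    if (abs(sum(object@prob) - 1) > 1e-12) return("probabilities must sum to 1")
    TRUE
})

#' SyntheticTruth: ternary ground-truth network chain
#'
#' Ground truth for the synthetic benchmark: K ternary {-1, 0, +1} incidence
#' matrices generated as a Markov chain over states, plus the generation
#' parameters and seed.
#'
#' @slot networks list of K integer matrices (drivers x targets) in {-1,0,1}.
#' @slot params list: edgeProbs, transitionProbs, negbin (size, prob), noiseSd.
#' @slot seed integer.
#' @export
setClass("SyntheticTruth",
    representation(networks = "list", params = "list", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    for (W in object@networks)
        if (!all(W %in% c(-1, 0, 1))) return("network entries must be in {-1,0,+1}")
    d <- unique(lapply(object@networks, dim))
    if (length(d) != 1L) return("all networks must share dimensions")
    TRUE
})

#' FitReport: solver diagnostics and held-out goodness of fit
#'
#' @slot objectiveTrace objective value after each full pass.
#' @slot adjustedR2 targets x phenotypes matrix of held-out adjusted R-squared
#'   (all-NA when no test cells were supplied).
#' @slot medianAdjustedR2 scalar summary.
#' @slot driversPerTarget integer count of retained drivers per target.
#' @export
setClass("FitReport",
    representation(objectiveTrace = "numeric", adjustedR2 = "matrix",
                   medianAdjustedR2 = "numeric", driversPerTarget = "integer"))
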