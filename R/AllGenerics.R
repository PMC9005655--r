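#' @rdname GRNExperiment
#' @param x a \code{GRNExperiment}.
#' @export
setGeneric("driverGenes", function(x) standardGeneric("driverGenes"))

#' @rdname GRNExperiment
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname GRNExperiment
#' @export
setGeneric("phenotypeOrder", function(x) standardGeneric("phenotypeOrder"))

#' @rdname GRNExperiment
#' @export
setGeneric("cellPhenotypes", function(x) standardGeneric("cellPhenotypes"))

#' @rdname GRNExperiment
#' @export
setGeneric("cellClusters", function(x) standardGeneric("cellClusters"))

#' @rdname GRNExperiment
#' @param phenotype a label from \code{phenotypeOrder(x)}, or \code{NULL} for
#'   all cells.
#' @param cells optional subset of cell ids.
#' @export
setGeneric("driverMatrix",
    function(x, phenotype = NULL, cells = NULL) standardGeneric("driverMatrix"))

#' @rdname GRNExperiment
#' @export
setGeneric("targetMatrix",
    function(x, phenotype = NULL, cells = NULL) standardGeneric("targetMatrix"))

#' @rdname IncidenceMatrixSet-accessors
#' @param x an \code{IncidenceMatrixSet}.
#' @param withBias keep the trailing \code{"(bias)"} row?
#' @export
setGeneric("incidenceMatrix",
    function(x, phenotype, withBias = TRUE) standardGeneric("incidenceMatrix"))

#' @rdname ActivityScoreSet-accessors
#' @param x an \code{ActivityScoreSet}.
#' @param phenotype a phenotype label.
#' @export
setGeneric("activityScores",
    function(x, phenotype) standardGeneric("activityScores"))

#' @rdname SyntheticTruth-accessors
#' @param x a \code{SyntheticTruth}.
#' @param state state index in 1..K.
#' @export
setGeneric("trueNetwork", function(x, state) standardGeneric("trueNetwork"))
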