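#' Construct a GRNExperiment
#'
#' @param expression numeric matrix, genes x cells, with gene ids as rownames
#'   and cell ids as colnames. Must be fully observed (imputed upstream).
#' @param phenotype character vector of phenotype labels, one per cell (or a
#'   named vector; names are matched against cell ids).
#' @param phenotypeOrder ordered vector of distinct phenotype labels; the
#'   fused penalty couples consecutive entries.
#' @param drivers character vector of driver (TF) gene ids; all remaining
#'   genes become targets.
#' @param cluster optional per-cell cluster labels.
#'
#' @return a validated [GRNExperiment-class] object.
#' @examples
#' expr <- matrix(rpois(12, 5), 3, 4,
#'                dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' ds <- GRNExperiment(expr, phenotype = c("A", "A", "B", "B"),
#'                     phenotypeOrder = c("A", "B"), drivers = "g1")
#' driverGenes(ds)
#' @export
GRNExperiment <- function(expression, phenotype, phenotypeOrder, drivers,
                          cluster = NULL) {
    expression <- as.matrix(expression)
    if (is.null(rownames(expression)) || is.null(colnames(expression)))
        stop("expression must have gene rownames and cell colnames")
    if (!is.null(names(phenotype)))
        phenotype <- phenotype[colnames(expression)]
    if (length(phenotype) != ncol(expression))
        stop("one phenotype label per cell is required")
    drivers <- unique(as.character(drivers))
    missing_drv <- setdiff(drivers, rownames(expression))
    if (length(missing_drv))
        warning("driver gene(s) absent from the matrix: ",
                paste(missing_drv, collapse = ", "))
    drivers <- intersect(drivers, rownames(expression))
    if (!length(drivers)) stop("empty driver set")
    role <- ifelse(rownames(expression) %in% drivers, "driver", "target")
    cd <- DataFrame(phenotype = as.character(phenotype),
                    row.names = colnames(expression))
    if (!is.null(cluster)) {
        if (!is.null(names(cluster))) cluster <- cluster[colnames(expression)]
        cd$cluster <- as.character(cluster)
    }
    se <- SummarizedExperiment(
        assays = list(expression = expression),
        rowData = DataFrame(role = role, row.names = rownames(expression)),
        colData = cd)
    metadata(se)$phenotypeOrder <- as.character(phenotypeOrder)
    new("GRNExperiment", se)
}

#' @rdname GRNExperiment
#' @export
setMethod("driverGenes", "GRNExperiment", function(x)
    rownames(x)[rowData(x)$role == "driver"])

#' @rdname GRNExperiment
#' @export
setMethod("targetGenes", "GRNExperiment", function(x)
    rownames(x)[rowData(x)$role == "target"])

#' @rdname GRNExperiment
#' @export
setMethod("phenotypeOrder", "GRNExperiment", function(x)
    metadata(x)$phenotypeOrder)

#' @rdname GRNExperiment
#' @export
setMethod("cellPhenotypes", "GRNExperiment", function(x) {
    p <- colData(x)$phenotype
    names(p) <- colnames(x)
    p
})

#' @rdname GRNExperiment
#' @export
setMethod("cellClusters", "GRNExperiment", function(x) {
    cd <- colData(x)
    if (!"cluster" %in% colnames(cd)) return(NULL)
    cl <- cd$cluster
    names(cl) <- colnames(x)
    cl
})

.cellsOf <- function(x, phenotype = NULL, cells = NULL) {
    ids <- colnames(x)
    if (!is.null(phenotype))
        ids <- ids[colData(x)$phenotype == phenotype]
    if (!is.null(cells)) ids <- intersect(ids, cells)
    ids
}

# Internal math orientation is cells x genes (one row per cell).
.exprFor <- function(x, genes, phenotype, cells) {
    ids <- .cellsOf(x, phenotype, cells)
    t(SummarizedExperiment::assay(x, "expression")[genes, ids, drop = FALSE])
}

#' @rdname GRNExperiment
#' @export
setMethod("driverMatrix", "GRNExperiment", function(x, phenotype = NULL,
                                                    cells = NULL)
    .exprFor(x, driverGenes(x), phenotype, cells))

#' @rdname GRNExperiment
#' @export
setMethod("targetMatrix", "GRNExperiment", function(x, phenotype = NULL,
                                                    cells = NULL)
    .exprFor(x, targetGenes(x), phenotype, cells))

#' @export
setMethod("show", "GRNExperiment", function(object) {
    callNextMethod()
    cat("phenotypeOrder(", length(phenotypeOrder(object)), "): ",
        paste(phenotypeOrder(object), collapse = " -> "), "\n", sep = "")
    cat("drivers: ", length(driverGenes(object)),
        "  targets: ", length(targetGenes(object)), "\n", sep = "")
})

#' Collapse all phenotypes into a single state
#'
#' Returns the same cells and genes under one phenotype label, for fitting a
#' single network on the combined data (the "combined LASSO" baseline that
#' ignores state structure).
#'
#' @param x a [GRNExperiment-class].
#' @param label the single phenotype label to use.
#' @return a [GRNExperiment-class] with \code{phenotypeOrder(x) == label}.
#' @export
poolPhenotypes <- function(x, label = "all") {
    GRNExperiment(SummarizedExperiment::assay(x, "expression"),
                  phenotype = rep(label, ncol(x)),
                  phenotypeOrder = label,
                  drivers = driverGenes(x),
                  cluster = cellClusters(x))
}

#' Natural-log transform (log1p) of the expression assay
#'
#' Off by default throughout the package: input expression is assumed already
#' imputed and normalised upstream. Provided for users whose imputed matrices
#' are on the count scale.
#'
#' @param x a [GRNExperiment-class].
#' @return the object with \code{log(1 + expression)} in place.
#' @export
logTransform <- function(x) {
    stopifnot(is(x, "GRNExperiment"))
    SummarizedExperiment::assay(x, "expression") <-
        log1p(SummarizedExperiment::assay(x, "expression"))
    x
}
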