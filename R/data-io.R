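#' Read an expression dataset from disk
#'
#' Loads an imputed expression matrix, a cell-metadata table, and a driver
#' (transcription-factor) gene list, and assembles a validated
#' [GRNExperiment-class]. Two matrix dialects are accepted:
#' \itemize{
#'   \item dense TSV/CSV: first column \code{gene_id}, remaining columns one
#'     per cell (header row holds cell ids). With \code{cellsAsRows = TRUE}
#'     the transposed dialect (cells in rows) is accepted instead.
#'   \item Matrix Market: a \code{.mtx} coordinate file with companion
#'     \code{genes.tsv} and \code{barcodes.tsv} files in the same directory.
#' }
#'
#' Cells present in the matrix but absent from the metadata are dropped with
#' a warning. A metadata phenotype label not listed in \code{phenotypeOrder},
#' duplicate gene ids, or an empty driver set are errors.
#'
#' @param matrixPath path to the dense matrix or \code{.mtx} file.
#' @param metadataPath TSV with columns \code{cell_id}, \code{phenotype} and
#'   optionally \code{cluster}.
#' @param driverPath plain-text driver list, one gene symbol per line;
#'   \code{#} comments allowed.
#' @param phenotypeOrder ordered character vector of phenotype labels.
#' @param cellsAsRows dense matrix is cells x genes instead of genes x cells.
#' @return a [GRNExperiment-class].
#' @export
readGRNExperiment <- function(matrixPath, metadataPath, driverPath,
                              phenotypeOrder, cellsAsRows = FALSE) {
    if (!file.exists(driverPath)) stop("driver list not found: ", driverPath)
    drivers <- readLines(driverPath)
    drivers <- trimws(sub("#.*$", "", drivers))
    drivers <- drivers[nzchar(drivers)]
    if (!length(drivers)) stop("empty driver set")

    mat <- if (grepl("\\.mtx$", matrixPath)) {
        .readMTX(matrixPath)
    } else {
        .readDense(matrixPath, cellsAsRows)
    }
    if (anyDuplicated(rownames(mat))) stop("duplicate gene ids")

    meta <- data.table::fread(metadataPath, data.table = FALSE,
                              colClasses = "character")
    need <- c("cell_id", "phenotype")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns cell_id and phenotype")
    unknown <- setdiff(unique(meta$phenotype), phenotypeOrder)
    if (length(unknown))
        stop("phenotype label(s) not in the supplied ordering: ",
             paste(unknown, collapse = ", "))
    absent <- setdiff(colnames(mat), meta$cell_id)
    if (length(absent)) {
        warning(length(absent), " cell(s) absent from metadata were dropped")
        mat <- mat[, setdiff(colnames(mat), absent), drop = FALSE]
    }
    meta <- meta[match(colnames(mat), meta$cell_id), , drop = FALSE]
    cl <- if ("cluster" %in% colnames(meta)) meta$cluster else NULL
    GRNExperiment(mat, phenotype = meta$phenotype,
                  phenotypeOrder = phenotypeOrder,
                  drivers = drivers, cluster = cl)
}

.readDense <- function(path, cellsAsRows = FALSE) {
    dt <- data.table::fread(path, data.table = FALSE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
    if (cellsAsRows) m <- t(m)
    m
}

.readMTX <- function(path) {
    dir <- dirname(path)
    genes <- data.table::fread(file.path(dir, "genes.tsv"), header = FALSE,
                               data.table = FALSE)[[1L]]
    cells <- data.table::fread(file.path(dir, "barcodes.tsv"), header = FALSE,
                               data.table = FALSE)[[1L]]
    m <- as.matrix(Matrix::readMM(path))
    dimnames(m) <- list(as.character(genes), as.character(cells))
    m
}

#' Write an expression dataset to disk
#'
#' Inverse of [readGRNExperiment()]: writes the matrix (dense TSV or Matrix
#' Market triplet), the metadata TSV and the driver list into \code{dir}.
#'
#' @param x a [GRNExperiment-class].
#' @param dir output directory (created if needed).
#' @param format \code{"tsv"} (dense, genes x cells) or \code{"mtx"}.
#' @return \code{dir}, invisibly.
#' @export
writeGRNExperiment <- function(x, dir, format = c("tsv", "mtx")) {
    format <- match.arg(format)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mat <- SummarizedExperiment::assay(x, "expression")
    if (format == "tsv") {
        df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
        data.table::fwrite(df, file.path(dir, "expression.tsv"), sep = "\t")
    } else {
        Matrix::writeMM(Matrix::Matrix(mat, sparse = TRUE),
                        file.path(dir, "expression.mtx"))
        writeLines(rownames(mat), file.path(dir, "genes.tsv"))
        writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
    }
    meta <- data.frame(cell_id = colnames(x),
                       phenotype = cellPhenotypes(x))
    cl <- cellClusters(x)
    if (!is.null(cl)) meta$cluster <- cl
    data.table::fwrite(meta, file.path(dir, "metadata.tsv"), sep = "\t")
    writeLines(driverGenes(x), file.path(dir, "drivers.txt"))
    writeLines(phenotypeOrder(x), file.path(dir, "phenotype_order.txt"))
    invisible(dir)
}

#' Median absolute deviation from the mean
#'
#' The variability measure used for feature selection:
#' \code{median(|v - mean(v)|)}. Note that deviations are taken from the
#' MEAN, not from the median as in the conventional MAD (\code{stats::mad});
#' mean-centring is this package's documented default, and
#' \code{center = "median"} switches to the conventional definition.
#'
#' @param v non-empty numeric vector.
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return non-negative scalar; 0 for constant vectors.
#' @examples
#' madVariability(c(1, 2, 3, 4, 100))  # 20
#' @export
madVariability <- function(v, center = c("mean", "median")) {
    center <- match.arg(center)
    if (!length(v)) stop("empty vector")
    c0 <- if (center == "mean") mean(v) else stats::median(v)
    stats::median(abs(v - c0))
}

#' Select the most variable drivers and targets
#'
#' Restricts the dataset to the \code{nDrivers} driver genes and
#' \code{nTargets} target genes with the highest [madVariability()] across
#' all cells. Original gene order is preserved and ties are broken by
#' original gene index, so the selection is reproducible.
#'
#' @param x a [GRNExperiment-class].
#' @param nDrivers,nTargets counts to retain; must not exceed availability.
#' @param center passed to [madVariability()].
#' @return the restricted [GRNExperiment-class].
#' @export
selectFeaturesByMAD <- function(x, nDrivers, nTargets,
                                center = c("mean", "median")) {
    center <- match.arg(center)
    drv <- driverGenes(x)
    tgt <- targetGenes(x)
    if (nDrivers > length(drv) || nTargets > length(tgt))
        stop("requested more genes than available")
    mat <- SummarizedExperiment::assay(x, "expression")
    pick <- function(genes, k) {
        v <- apply(mat[genes, , drop = FALSE], 1L, madVariability,
                   center = center)
        # stable: order by decreasing MAD, ties by original index
        keep <- genes[order(-v, seq_along(v))[seq_len(k)]]
        genes[genes %in% keep]
    }
    keep <- rownames(x) %in% c(pick(drv, nDrivers), pick(tgt, nTargets))
    x[keep, ]
}

#' Phenotype-stratified train/test split
#'
#' Splits cells into training and testing sets within each phenotype at the
#' given ratio (80/20 by default), deterministically for a given seed.
#'
#' @param x a [GRNExperiment-class].
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return a [TrainTestSplit-class].
#' @export
splitTrainTest <- function(x, ratio = 0.8, seed = 1L) {
    stopifnot(ratio > 0, ratio < 1)
    ph <- cellPhenotypes(x)
    levels <- intersect(phenotypeOrder(x), unique(ph))
    train <- test <- stats::setNames(vector("list", length(levels)), levels)
    withr::with_seed(as.integer(seed), {
        for (lv in levels) {
            ids <- names(ph)[ph == lv]
            if (length(ids) < 2L)
                stop("phenotype '", lv, "' has fewer than 2 cells")
            ntr <- max(1L, min(length(ids) - 1L, round(ratio * length(ids))))
            tr <- sample(ids, ntr)
            train[[lv]] <- sort(tr)
            test[[lv]] <- sort(setdiff(ids, tr))
        }
    })
    new("TrainTestSplit", train = train, test = test, ratio = ratio,
        seed = as.integer(seed))
}

#' @describeIn splitTrainTest all training cell ids (across phenotypes).
#' @param split a \code{TrainTestSplit}.
#' @export
trainCells <- function(split) unlist(split@train, use.names = FALSE)

#' @describeIn splitTrainTest all test cell ids (across phenotypes).
#' @export
testCells <- function(split) unlist(split@test, use.names = FALSE)

#' @export
setMethod("show", "TrainTestSplit", function(object) {
    cat("TrainTestSplit (ratio ", object@ratio, ", seed ", object@seed,
        ")\n", sep = "")
    for (lv in names(object@train))
        cat("  ", lv, ": ", length(object@train[[lv]]), " train / ",
            length(object@test[[lv]]), " test\n", sep = "")
})
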