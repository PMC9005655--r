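# Independent oracles used to cross-check the package's own implementations.
# These deliberately share no code with the solver under test.

# Cyclic coordinate-descent LASSO for one response:
# minimises 0.5 * ||y - X w - b||^2 + lambda * ||w||_1 (intercept b free).
lassoCDOracle <- function(X, y, lambda, maxIter = 5000L, tol = 1e-10) {
    p <- ncol(X)
    w <- rep(0, p)
    b <- mean(y)
    xss <- colSums(X^2)
    for (it in seq_len(maxIter)) {
        wOld <- c(w, b)
        r <- y - X %*% w - b
        for (j in seq_len(p)) {
            rj <- r + X[, j] * w[j]
            zj <- sum(X[, j] * rj)
            wj <- sign(zj) * max(abs(zj) - lambda, 0) / xss[j]
            r <- rj - X[, j] * wj
            w[j] <- wj
        }
        bNew <- b + mean(r)
        r <- r - (bNew - b)
        b <- bNew
        if (max(abs(c(w, b) - wOld)) < tol) break
    }
    list(w = w, b = b)
}

# HITS authority via direct eigendecomposition of t(A) %*% A on the
# absolute adjacency; hub = A %*% authority. Both scaled to unit maximum.
hitsOracle <- function(A) {
    A <- abs(A)
    e <- eigen(crossprod(A), symmetric = TRUE)
    a <- abs(e$vectors[, 1L])
    h <- as.numeric(A %*% a)
    list(authority = a / max(a), hub = h / max(h))
}

# Small deterministic dataset built in code (no fixtures on disk).
makeToyDataset <- function(m = 3L, n = 4L, K = 2L, cellsPerState = 30L,
                           seed = 42L) {
    truth <- generateGRNChain(K = K, m = m, n = n, pFlip = 0.2, pToZero = 0.3,
                              noiseSd = 0.5, seed = seed)
    simulateExpression(truth, cellsPerState, seed = seed + 1L)
}

# Dense TSV + metadata + driver-list files for reader tests; returns paths.
writeToyFiles <- function(dir, mat, phenotype, drivers, cluster = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    write.table(df, file.path(dir, "expr.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    meta <- data.frame(cell_id = colnames(mat), phenotype = phenotype)
    if (!is.null(cluster)) meta$cluster <- cluster
    write.table(meta, file.path(dir, "meta.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines(c("# driver genes", drivers), file.path(dir, "drivers.txt"))
    list(matrix = file.path(dir, "expr.tsv"),
         meta = file.path(dir, "meta.tsv"),
         drivers = file.path(dir, "drivers.txt"))
}
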