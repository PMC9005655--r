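#' Represent a fitted incidence matrix as a weighted bipartite graph
#'
#' Builds a directed driver-to-target igraph with one edge per retained
#' non-zero weight. Edges carry the signed weight (\code{weight}) and its
#' sign (\code{sign}; +1 activation, -1 repression). All drivers and targets
#' are present as vertices even when isolated; vertex attribute \code{role}
#' distinguishes the two sides.
#'
#' @param W incidence matrix ((m+1) x n with a trailing \code{"(bias)"} row,
#'   or m x n); the bias row is excluded.
#' @param filter optional [RegulonFilter-class]; \code{state} selects which
#'   of its per-phenotype masks to apply.
#' @param state state index into \code{filter} (default 1).
#' @param phenotype optional label stored as a graph attribute.
#' @return an \code{igraph} object.
#' @export
buildBipartiteGraph <- function(W, filter = NULL, state = 1L,
                                phenotype = NULL) {
    if (!is.null(rownames(W)) && rownames(W)[nrow(W)] == "(bias)")
        W <- W[-nrow(W), , drop = FALSE]
    if (is.null(rownames(W))) rownames(W) <- paste0("driver", seq_len(nrow(W)))
    if (is.null(colnames(W))) colnames(W) <- paste0("target", seq_len(ncol(W)))
    if (!is.null(filter)) {
        W[!filter@keepDrivers[[state]]] <- 0
        W[, !filter@keepTargets] <- 0
    }
    nz <- which(W != 0, arr.ind = TRUE)
    edges <- data.frame(from = rownames(W)[nz[, 1L]],
                        to = colnames(W)[nz[, 2L]],
                        weight = W[nz], sign = sign(W[nz]))
    vertices <- data.frame(
        name = c(rownames(W), colnames(W)),
        role = rep(c("driver", "target"), c(nrow(W), ncol(W))))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = vertices)
    if (!is.null(phenotype)) g <- igraph::set_graph_attr(g, "phenotype",
                                                         phenotype)
    g
}

#' Kleinberg authority and hub scores of a bipartite regulatory network
#'
#' HITS centralities on the absolute edge weights (the iteration requires a
#' non-negative adjacency; signs are kept on the edges for reporting).
#' Scores are scaled to unit maximum. In a driver-to-target graph, hub mass
#' concentrates on drivers and authority mass on targets.
#'
#' @param g an igraph from [buildBipartiteGraph()] with at least one edge.
#' @return data.frame with columns \code{gene}, \code{role},
#'   \code{authority}, \code{hub}.
#' @export
authorityHubScores <- function(g) {
    if (igraph::ecount(g) == 0L) stop("graph has no edges")
    h <- igraph::hits_scores(g, weights = abs(igraph::E(g)$weight),
                             scale = TRUE)
    data.frame(gene = igraph::V(g)$name,
               role = igraph::V(g)$role,
               authority = unname(h$authority[igraph::V(g)$name]),
               hub = unname(h$hub[igraph::V(g)$name]),
               row.names = NULL)
}

#' Compare centrality scores between two phenotypes
#'
#' Pairs genes shared by the two reports and applies a two-sided Wilcoxon
#' signed-rank test to the paired authority scores and to the paired hub
#' scores; the two p-values are Benjamini-Hochberg adjusted. Identical score
#' vectors (all differences zero) give p = 1 by convention.
#'
#' @param reportA,reportB outputs of [authorityHubScores()] (or named
#'   numeric vectors, treated as authority scores).
#' @param alpha FDR level for the verdict.
#' @return list with \code{perGene} (gene, authority/hub deltas),
#'   \code{tests} (score, p, q), and \code{significant} (any q < alpha).
#' @export
compareCentrality <- function(reportA, reportB, alpha = 0.05) {
    asDF <- function(r) {
        if (is.data.frame(r)) return(r)
        data.frame(gene = names(r), authority = as.numeric(r), hub = NA_real_)
    }
    a <- asDF(reportA); b <- asDF(reportB)
    genes <- intersect(a$gene, b$gene)
    if (length(genes) < 2L) stop("fewer than 2 shared genes")
    a <- a[match(genes, a$gene), ]; b <- b[match(genes, b$gene), ]
    testOne <- function(x, y) {
        if (all(is.na(x)) || all(is.na(y))) return(NA_real_)
        if (isTRUE(all.equal(x, y))) return(1)
        suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
    }
    p <- c(authority = testOne(a$authority, b$authority),
           hub = testOne(a$hub, b$hub))
    q <- stats::p.adjust(p, method = "BH")
    list(perGene = data.frame(gene = genes,
                              deltaAuthority = b$authority - a$authority,
                              deltaHub = b$hub - a$hub),
         tests = data.frame(score = names(p), p = unname(p), q = unname(q)),
         significant = any(q < alpha, na.rm = TRUE))
}

#' Export a fitted network as an edge-list TSV (and optionally GraphML)
#'
#' @param g an igraph from [buildBipartiteGraph()].
#' @param path output TSV path; with \code{graphml = TRUE} a sibling
#'   \code{.graphml} file is written as well.
#' @param graphml also write GraphML.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(g, path, graphml = FALSE) {
    el <- igraph::as_data_frame(g, what = "edges")
    colnames(el)[1:2] <- c("driver", "target")
    data.table::fwrite(el, path, sep = "\t")
    if (graphml)
        igraph::write_graph(g, sub("\\.tsv$", ".graphml", path),
                            format = "graphml")
    invisible(path)
}
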