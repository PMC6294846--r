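#' Spearman rank correlation matrix over a gene subset
#'
#' Computes the Spearman rank correlation coefficient (SRCC) — the Pearson
#' correlation of mid-ranks, ties receiving average ranks — between all
#' pairs of the requested genes across all samples. A constant gene has
#' undefined rank correlations; these are reported as 0 with a warning so
#' the matrix keeps its full shape.
#'
#' @param em An [expression_matrix()] with at least 3 samples.
#' @param gene_subset Gene ids to correlate (default: all genes).
#' @return Symmetric numeric matrix with unit diagonal, dimnames set to
#'   the gene ids.
#' @export
spearman_matrix <- function(em, gene_subset = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(gene_subset)) gene_subset <- rownames(em$values)
  missing <- setdiff(gene_subset, rownames(em$values))
  if (length(missing))
    stop("genes not in matrix: ", paste(missing, collapse = ", "))
  if (ncol(em$values) < 3L)
    stop("need at least 3 samples for rank correlation")
  x <- t(em$values[gene_subset, , drop = FALSE])
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (anyNA(rho)) {
    warning("constant gene(s) with undefined rank correlation; ",
            "reporting 0 for the affected pairs")
    rho[is.na(rho)] <- 0
  }
  diag(rho) <- 1
  rho
}

#' Build the complete weighted co-expression network
#'
#' Every unordered gene pair becomes one edge weighted by its SRCC, so a
#' network over n genes always has n(n-1)/2 edges (81 genes give 3240).
#'
#' @param srcc Symmetric correlation matrix with unit diagonal and gene
#'   dimnames, e.g. from [spearman_matrix()].
#' @return An object of class `coexpression_network`: a list with `nodes`
#'   (gene ids) and `edges` (data.frame `gene_a`, `gene_b`, `weight`,
#'   `abs_weight`).
#' @export
build_network <- function(srcc) {
  if (!is.matrix(srcc) || nrow(srcc) != ncol(srcc))
    stop("`srcc` must be a square matrix")
  if (nrow(srcc) < 2L)
    stop("network error: need at least 2 genes")
  if (is.null(rownames(srcc)))
    stop("`srcc` needs gene dimnames")
  if (max(abs(srcc - t(srcc))) > 1e-10)
    stop("`srcc` must be symmetric")
  ids <- rownames(srcc)
  ut <- which(upper.tri(srcc), arr.ind = TRUE)
  edges <- data.frame(gene_a = ids[ut[, 1L]],
                      gene_b = ids[ut[, 2L]],
                      weight = srcc[ut],
                      stringsAsFactors = FALSE)
  edges$abs_weight <- abs(edges$weight)
  structure(list(nodes = ids, edges = edges),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees and the top-k hub genes
#'
#' Counts incident edges per node and returns nodes sorted by degree
#' (descending), ties broken by gene id (ascending) so the ranking is
#' deterministic.
#'
#' @param net A `coexpression_network`.
#' @param top_k How many top nodes to return (default 7, the usual hub
#'   highlight count); if larger than the node count, all nodes are
#'   returned.
#' @return data.frame `gene`, `degree`, sorted as described.
#' @export
node_degrees <- function(net, top_k = 7L) {
  stopifnot(inherits(net, "coexpression_network"))
  if (length(net$nodes) == 0L) stop("network error: empty network")
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$nodes))
  df <- data.frame(gene = names(deg), degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, min(top_k, nrow(df)))
}

#' Extract the high-weight subnetwork
#'
#' Keeps edges whose weight strictly exceeds `min_weight` — by default on
#' the absolute SRCC, since strong anti-correlation is co-expression
#' evidence too — and drops nodes left without any edge.
#'
#' @param net A `coexpression_network`.
#' @param min_weight Strict threshold in [0, 1] (default 0.8).
#' @param signed If `TRUE`, threshold the signed weight instead (only
#'   strongly positive edges survive).
#' @return A `coexpression_network` (possibly with no edges).
#' @export
threshold_subnetwork <- function(net, min_weight = 0.8, signed = FALSE) {
  stopifnot(inherits(net, "coexpression_network"))
  if (min_weight < 0 || min_weight > 1)
    stop("min_weight must be in [0, 1]")
  w <- if (signed) net$edges$weight else net$edges$abs_weight
  edges <- net$edges[w > min_weight, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  if (nrow(edges) == 0L)
    message("threshold_subnetwork: no edge exceeds ", min_weight)
  structure(list(nodes = nodes, edges = edges),
            class = "coexpression_network")
}

#' Convert a co-expression network to an igraph object
#' @param net A `coexpression_network`.
#' @return An undirected weighted [igraph::graph].
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coexpression_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "weight", "abs_weight")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  g
}

#' Network and matrix exports
#'
#' `write_edge_list` writes a TSV edge list (`gene_a`, `gene_b`, `weight`,
#' `abs_weight`); `write_graphml` writes GraphML readable by Cytoscape;
#' `write_srcc_matrix` writes the full correlation matrix as TSV for
#' heat-map rendering.
#'
#' @param net A `coexpression_network`.
#' @param srcc A correlation matrix from [spearman_matrix()].
#' @param path Output path.
#' @name network-export
NULL

#' @rdname network-export
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname network-export
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname network-export
#' @export
write_srcc_matrix <- function(srcc, path) {
  df <- data.frame(gene_id = rownames(srcc), srcc, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
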