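#' @importFrom Matrix sparseMatrix colSums rowSums t Diagonal
NULL

# Shared constructor: edges is a data.frame(gene_a, gene_b, score) already
# thresholded/merged; nodes may extend beyond genes appearing in edges.
new_ppi_network <- function(edges, nodes = NULL, score_threshold = NA_real_) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  i <- match(edges$gene_a, nodes)
  j <- match(edges$gene_b, nodes)
  n <- length(nodes)
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(edges$score, 2L),
                              dims = c(n, n), dimnames = list(nodes, nodes))
  structure(list(nodes = nodes, edges = edges, adjacency = adj,
                 W = column_normalize(adj),
                 score_threshold = score_threshold),
            class = "ppi_network")
}

#' Read a STRING-style scored edge list and build the interaction network
#'
#' Expects three whitespace- or tab-separated columns: the two interactor
#' gene symbols and a combined confidence score. Scores on the STRING
#' integer convention (0-1000) are detected (any score > 1) and divided by
#' 1000 before thresholding. Edges whose score is not strictly greater than
#' `score_threshold` are dropped, duplicate and reversed pairs are merged
#' keeping the maximum score, and self-loops are removed. The returned
#' network carries both the symmetric weighted adjacency matrix and its
#' column-normalized form used by the random walk (each non-isolated
#' column sums to 1).
#'
#' @param path edge-list file; a header line is auto-detected.
#' @param score_threshold retain edges with score strictly above this value
#'   (on the 0-1 scale). Default 0.7, the usual high-confidence cutoff.
#' @param binarize if TRUE, retained edges are given weight 1 instead of
#'   their score.
#' @param largest_component if TRUE, restrict to the largest connected
#'   component.
#' @return an object of class `ppi_network` with elements `nodes`, `edges`,
#'   `adjacency`, `W` (column-normalized adjacency) and `score_threshold`.
#' @export
read_string_edges <- function(path, score_threshold = 0.7, binarize = FALSE,
                              largest_component = FALSE) {
  if (!file.exists(path)) {
    stop_netstrat(sprintf("edge file not found: %s", path),
                  "netstrat_format_error")
  }
  first <- readLines(path, n = 1L)
  f1 <- strsplit(trimws(first), "[\t ]+")[[1]]
  has_header <- length(f1) >= 3 && is.na(suppressWarnings(as.numeric(f1[3])))
  df <- utils::read.table(path, header = has_header, sep = "",
                          stringsAsFactors = FALSE, comment.char = "#",
                          colClasses = c("character", "character", "character"))
  if (ncol(df) < 3) {
    stop_netstrat("edge list must have 3 columns (gene_a, gene_b, score)",
                  "netstrat_format_error")
  }
  names(df)[1:3] <- c("gene_a", "gene_b", "score")
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1] + has_header
    stop_netstrat(sprintf("non-numeric score at line %d", bad),
                  "netstrat_format_error")
  }
  if (any(score > 1)) score <- score / 1000
  df$score <- score
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  # canonical orientation, merge duplicates keeping the max score
  a <- pmin(df$gene_a, df$gene_b); b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -df$score)
  keep <- !duplicated(key[o])
  edges <- data.frame(gene_a = a[o][keep], gene_b = b[o][keep],
                      score = df$score[o][keep], stringsAsFactors = FALSE)
  edges <- edges[edges$score > score_threshold, , drop = FALSE]
  if (nrow(edges) == 0) {
    stop_netstrat("no edges survive the score threshold",
                  "netstrat_data_error")
  }
  if (binarize) edges$score <- 1
  net <- new_ppi_network(edges, score_threshold = score_threshold)
  if (largest_component) {
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
    comp <- igraph::components(g)
    keep_nodes <- names(comp$membership)[comp$membership == which.max(comp$csize)]
    keep_edge <- net$edges$gene_a %in% keep_nodes & net$edges$gene_b %in% keep_nodes
    net <- new_ppi_network(net$edges[keep_edge, , drop = FALSE],
                           score_threshold = score_threshold)
  }
  net
}

#' Column-normalize an adjacency matrix
#'
#' Divides each column by its sum so the matrix becomes column-stochastic
#' on non-isolated nodes, as the random-walk transition matrix requires.
#' All-zero columns (isolated nodes) are left zero and reported in the
#' `isolated` attribute.
#'
#' @param adjacency square symmetric nonnegative matrix (dense or sparse).
#' @return matrix of the same storage class with unit column sums where
#'   defined; attribute `isolated` holds the isolated node names/indices.
#' @export
column_normalize <- function(adjacency) {
  if (nrow(adjacency) != ncol(adjacency)) {
    stop_netstrat("adjacency must be square", "netstrat_data_error")
  }
  mn <- if (methods::is(adjacency, "sparseMatrix")) {
    if (length(adjacency@x)) min(adjacency@x, 0) else 0
  } else min(adjacency)
  if (mn < 0) {
    stop_netstrat("adjacency has negative entries", "netstrat_data_error")
  }
  cs <- Matrix::colSums(adjacency)
  isolated <- which(cs == 0)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  if (is.matrix(adjacency)) {
    W <- adjacency * rep(scale, each = nrow(adjacency))
  } else {
    W <- adjacency %*% Matrix::Diagonal(x = scale)
  }
  dimnames(W) <- dimnames(adjacency)
  iso_names <- if (!is.null(colnames(adjacency))) colnames(adjacency)[isolated] else isolated
  attr(W, "isolated") <- iso_names
  W
}

#' Restrict a mutation matrix to genes present in a network
#'
#' @param mutations binary patients-by-genes matrix.
#' @param network a `ppi_network`.
#' @return list with `matrix` (columns restricted to the network node set),
#'   `dropped_genes` (symbols absent from the network) and
#'   `flagged_patients` (patients whose entire mutated gene set was dropped).
#' @export
intersect_with_network <- function(mutations, network) {
  stopifnot(inherits(network, "ppi_network"))
  keep <- colnames(mutations) %in% network$nodes
  restricted <- mutations[, keep, drop = FALSE]
  flagged <- rownames(mutations)[rowSums(restricted) == 0]
  list(matrix = restricted,
       dropped_genes = colnames(mutations)[!keep],
       flagged_patients = flagged)
}

#' Summarize a network (nodes, edges, connected components)
#'
#' @param network a `ppi_network`.
#' @return list with `n_nodes`, `n_edges`, `n_components`,
#'   `largest_component`.
#' @export
network_summary <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges[, 1:2], directed = FALSE,
    vertices = data.frame(name = network$nodes))
  comp <- igraph::components(g)
  list(n_nodes = length(network$nodes), n_edges = nrow(network$edges),
       n_components = comp$no, largest_component = max(comp$csize))
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges (score > %s)\n",
              length(x$nodes), nrow(x$edges),
              format(x$score_threshold)))
  invisible(x)
}
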