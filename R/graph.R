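#' Weighted synaptic graph
#'
#' Container for a symmetric, non-negative weighted adjacency matrix over
#' neuron IDs. Weights are expressed as multiples of the contact-area
#' threshold that defines unit link weight, so a weight of 2 means twice the
#' threshold area.
#'
#' @param A numeric square matrix of link weights; must be symmetric within
#'   `tol`, with zero diagonal and no negative entries.
#' @param ids integer node (neuron) IDs, one per matrix row. Defaults to
#'   existing dimnames or `1:nrow(A)`.
#' @param threshold contact-area threshold (um^2) that defines unit weight,
#'   or `NA` when unknown (e.g. a toy matrix).
#' @param tol symmetry tolerance.
#' @return An object of class `weighted_graph`: a list with elements `ids`
#'   (integer vector), `A` (dense matrix with IDs as dimnames) and
#'   `threshold` (um^2).
#' @export
weighted_graph <- function(A, ids = NULL, threshold = NA_real_, tol = 1e-9) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("adjacency matrix must be square, got ", nrow(A), " x ", ncol(A))
  }
  if (!is.numeric(A)) stop("adjacency matrix must be numeric")
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(A))) suppressWarnings(as.integer(rownames(A))) else seq_len(nrow(A))
    if (anyNA(ids)) ids <- seq_len(nrow(A))
  }
  ids <- as.integer(ids)
  if (length(ids) != nrow(A)) stop("length(ids) must equal nrow(A)")
  if (anyDuplicated(ids)) stop("node ids must be unique")
  asym <- abs(A - t(A))
  if (any(asym > tol)) {
    worst <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "adjacency not symmetric: worst pair (%d, %d), |A(i,j) - A(j,i)| = %g",
      ids[worst[1]], ids[worst[2]], max(asym)
    ))
  }
  A <- (A + t(A)) / 2   # remove sub-tolerance asymmetry
  if (any(A < 0)) stop("negative link weights are not allowed")
  diag(A) <- 0
  dimnames(A) <- list(ids, ids)
  structure(
    list(ids = ids, A = A, threshold = threshold),
    class = "weighted_graph"
  )
}

#' @export
print.weighted_graph <- function(x, ...) {
  e <- sum(x$A[upper.tri(x$A)] > 0)
  cat(sprintf(
    "<weighted_graph> %d nodes, %d links, threshold %s um^2\n",
    length(x$ids), e,
    if (is.na(x$threshold)) "NA" else format(x$threshold)
  ))
  invisible(x)
}

#' Number of nodes of a weighted graph
#' @param graph a [weighted_graph()].
#' @return integer node count.
#' @export
n_nodes <- function(graph) length(graph$ids)

#' Edge list of a weighted graph
#'
#' @param graph a [weighted_graph()].
#' @return data.frame with columns `i`, `j` (neuron IDs, `i < j`) and
#'   `weight`, one row per link.
#' @export
graph_edges <- function(graph) {
  idx <- which(upper.tri(graph$A) & graph$A > 0, arr.ind = TRUE)
  out <- data.frame(
    i = graph$ids[idx[, 1]],
    j = graph$ids[idx[, 2]],
    weight = graph$A[idx]
  )
  out[order(out$i, out$j), , drop = FALSE]
}

#' Convert to an igraph object
#'
#' @param graph a [weighted_graph()].
#' @return an undirected weighted [igraph::graph] whose vertex `name`s are
#'   the neuron IDs.
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_adjacency_matrix(
    graph$A, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  g
}

#' Restrict a graph to a subset of nodes
#' @param graph a [weighted_graph()].
#' @param ids node IDs to keep.
#' @return the induced `weighted_graph`.
#' @export
subgraph_of <- function(graph, ids) {
  keep <- match(ids, graph$ids)
  if (anyNA(keep)) {
    stop("unknown node id(s): ", paste(ids[is.na(keep)], collapse = ", "))
  }
  weighted_graph(graph$A[keep, keep, drop = FALSE],
                 ids = graph$ids[keep], threshold = graph$threshold)
}

# internal: ids of nodes with at least one link
linked_ids <- function(graph) graph$ids[rowSums(graph$A) > 0]
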