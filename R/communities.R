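#' Newman modularity of a partition
#'
#' `Q = (1/2W) sum_ij [A_ij - k_i k_j / (2W)] delta(c_i, c_j)` with
#' `2W = sum_i k_i`: the excess fraction of within-module weight over the
#' degree-preserving random null.
#'
#' @param graph a [weighted_graph()].
#' @param partition a [node_partition()] covering the graph's nodes.
#' @return modularity Q in `[-0.5, 1]`.
#' @export
modularity_Q <- function(graph, partition) {
  if (sum(graph$A) == 0) stop("graph has no links: Q undefined")
  m <- aligned_membership(graph, partition)
  g <- as_igraph(graph)
  igraph::modularity(g, membership = m, weights = igraph::E(g)$weight)
}

#' Girvan-Newman divisive decomposition
#'
#' Iteratively removes the link with highest edge betweenness (recomputed
#' after each removal) until the graph falls into `target_modules`
#' components. Betweenness uses the same inverse-weight traversal lengths
#' as [betweenness_centrality()].
#'
#' @param graph a [weighted_graph()].
#' @param target_modules desired module count.
#' @param use_weights use inverse-weight lengths (default `TRUE`).
#' @return a [node_partition()]. If the target is unreachable the best
#'   achieved split is returned with a warning.
#' @export
girvan_newman <- function(graph, target_modules, use_weights = TRUE) {
  g <- as_igraph(graph)
  lengths_ <- if (use_weights) 1 / igraph::E(g)$weight else NA
  comm <- igraph::cluster_edge_betweenness(
    g, weights = lengths_, directed = FALSE,
    merges = TRUE, modularity = FALSE, membership = FALSE
  )
  memb <- tryCatch(
    igraph::cut_at(comm, no = target_modules),
    error = function(e) {
      warning("target of ", target_modules,
              " modules unreachable; returning components")
      igraph::components(g)$membership
    }
  )
  names(memb) <- igraph::V(g)$name
  node_partition(memb, method = "girvan_newman")
}

#' Fast greedy (CNM) agglomerative decomposition
#'
#' Greedy modularity-maximizing merges; returns the maximum-Q cut of the
#' merge dendrogram.
#'
#' @param graph a [weighted_graph()].
#' @return a [node_partition()].
#' @export
cnm_agglomerative <- function(graph) {
  g <- as_igraph(graph)
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(comm)
  names(memb) <- igraph::V(g)$name
  node_partition(memb, method = "cnm_agglomerative")
}

#' Spectral decomposition by k-means on graph eigenvectors
#'
#' Clusters the rows of the `k` leading eigenvectors of either the graph
#' Laplacian `L = D - A` (eigenvectors of the smallest nonzero eigenvalues)
#' or the modularity matrix `B = A - k k^T / 2W` (largest positive
#' eigenvalues only). When `k` is `NULL` the module count is scanned over
#' `k_range` and the partition with maximal modularity Q is returned.
#'
#' @param graph a [weighted_graph()].
#' @param k module count, or `NULL` to scan.
#' @param basis `"laplacian"` or `"modularity_matrix"`.
#' @param k_range candidate module counts for the scan.
#' @param nstart k-means restarts (default 20).
#' @param seed RNG seed for k-means.
#' @return a [node_partition()] with attribute `quality_scan` (data.frame
#'   `k`, `Q`) when a scan was performed.
#' @export
spectral_partition <- function(graph, k = NULL,
                               basis = c("laplacian", "modularity_matrix"),
                               k_range = 2:20, nstart = 20, seed = 1L) {
  basis <- match.arg(basis)
  A <- graph$A
  n <- nrow(A)
  deg <- rowSums(A)
  if (basis == "laplacian") {
    M <- diag(deg) - A
    es <- eigen(M, symmetric = TRUE)
    # ascending order, skip the null space (one zero per component)
    vals <- rev(es$values)
    vecs <- es$vectors[, rev(seq_len(n)), drop = FALSE]
    nonzero <- which(vals > 1e-9)
  } else {
    M <- A - outer(deg, deg) / sum(deg)
    es <- eigen(M, symmetric = TRUE)
    vals <- es$values
    vecs <- es$vectors
    nonzero <- which(vals > 1e-9)
  }
  if (length(nonzero) == 0) stop("no usable eigenvectors for basis ", basis)

  run_k <- function(kk) {
    take <- nonzero[seq_len(min(kk, length(nonzero)))]
    X <- vecs[, take, drop = FALSE]
    cl <- stats::kmeans(X, centers = kk, nstart = nstart)$cluster
    names(cl) <- graph$ids
    node_partition(cl, method = paste0("spectral_", basis), seed = seed)
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  if (!is.null(k)) {
    if (k < 2 || k > n) stop("k must be in [2, N]")
    return(run_k(k))
  }
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  scan <- data.frame(k = k_range, Q = NA_real_)
  best <- NULL
  best_Q <- -Inf
  for (i in seq_along(k_range)) {
    part <- run_k(k_range[i])
    scan$Q[i] <- modularity_Q(graph, part)
    if (scan$Q[i] > best_Q) {
      best_Q <- scan$Q[i]
      best <- part
    }
  }
  attr(best, "quality_scan") <- scan
  best
}

#' Participation coefficients
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2` where `k_im` is the summed link weight
#' from node `i` into module `m`. High values (near 1) mean a node's links
#' are spread across modules; 0 means all weight stays in one module.
#' Isolated nodes get `P_i = 0`.
#'
#' @param graph a [weighted_graph()].
#' @param partition a [node_partition()].
#' @return named numeric vector of `P_i`, names = node IDs.
#' @export
participation_coefficients <- function(graph, partition) {
  m <- aligned_membership(graph, partition)
  mods <- sort(unique(m))
  ind <- outer(m, mods, "==") * 1
  K_im <- graph$A %*% ind             # N x M weight into each module
  k <- rowSums(graph$A)
  P <- rep(0, length(k))
  pos <- k > 0
  P[pos] <- 1 - rowSums((K_im[pos, , drop = FALSE] / k[pos])^2)
  P <- pmin(pmax(P, 0), 1)   # clip round-off outside [0, 1]
  stats::setNames(P, graph$ids)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the contingency
#' table of the two labelings; 1 for identical partitions, about 0 for
#' independent ones.
#'
#' @param p1,p2 [node_partition()]s over the same node set (or named
#'   membership vectors).
#' @return the adjusted Rand index in `[-1, 1]`.
#' @export
partition_similarity <- function(p1, p2) {
  m1 <- if (inherits(p1, "node_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "node_partition")) p2$membership else p2
  if (is.null(names(m1)) || is.null(names(m2))) {
    if (length(m1) != length(m2)) stop("partitions cover different node sets")
  } else {
    if (!setequal(names(m1), names(m2))) {
      stop("partitions cover different node sets")
    }
    m2 <- m2[names(m1)]
  }
  tab <- table(m1, m2)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < 1e-15) return(1)  # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}
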