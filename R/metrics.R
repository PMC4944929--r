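#' Node degree and strength
#'
#' Unweighted degree is the number of links incident on a neuron; weighted
#' degree (strength) is the row sum of the adjacency matrix,
#' `k_i = sum_j A(i, j)`.
#'
#' @param graph a [weighted_graph()].
#' @return data.frame with columns `node`, `degree` (integer link count)
#'   and `k` (weighted degree).
#' @export
weighted_degree <- function(graph) {
  data.frame(
    node = graph$ids,
    degree = as.integer(rowSums(graph$A > 0)),
    k = rowSums(graph$A)
  )
}

#' Node and edge betweenness centrality
#'
#' Counts the shortest paths between all node pairs that traverse a node
#' (nBC) or a link (eBC), with fractional credit shared among tied
#' geodesics. Counts are unnormalized pair counts over unordered pairs and
#' exclude the path endpoints. On the weighted network the traversal length
#' of a link defaults to the inverse of its weight, so heavy links are
#' short.
#'
#' @param graph a [weighted_graph()].
#' @param use_weights compute over the weighted network (default `TRUE`).
#' @param length_rule `"inverse_weight"` (link length `1/weight`) or
#'   `"unit"` (hop counting even when `use_weights`).
#' @param normalized divide by the number of pairs excluding the
#'   node/endpoints (default `FALSE`, plain counts).
#' @return list with `nodes` (data.frame `node`, `nbc`) and `edges`
#'   (data.frame `i`, `j`, `weight`, `ebc`).
#' @export
betweenness_centrality <- function(graph, use_weights = TRUE,
                                   length_rule = c("inverse_weight", "unit"),
                                   normalized = FALSE) {
  length_rule <- match.arg(length_rule)
  g <- as_igraph(graph)
  w <- igraph::E(g)$weight
  lengths_ <- if (use_weights && length_rule == "inverse_weight") {
    if (any(w <= 0)) stop("inverse_weight lengths need strictly positive link weights")
    1 / w
  } else {
    NA  # igraph: NA = ignore weights, hop counting
  }
  nbc <- igraph::betweenness(g, weights = lengths_, normalized = normalized)
  ebc <- igraph::edge_betweenness(g, weights = lengths_)
  el <- igraph::as_edgelist(g, names = TRUE)
  nodes <- data.frame(node = as.integer(igraph::V(g)$name), nbc = unname(nbc))
  edges <- data.frame(
    i = pmin(as.integer(el[, 1]), as.integer(el[, 2])),
    j = pmax(as.integer(el[, 1]), as.integer(el[, 2])),
    weight = w, ebc = unname(ebc)
  )
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Shortest-path census over the unweighted topology
#'
#' Breadth-first geodesic lengths between all ordered node pairs; pairs in
#' different components are tallied as disconnected.
#'
#' @param graph a [weighted_graph()].
#' @return list with `census` (data.frame `length`, `n_pairs`,
#'   `pct_connected` -- percentages over connected ordered pairs),
#'   `n_connected_pairs`, `n_disconnected_pairs`, `n_ordered_pairs`.
#' @export
shortest_path_census <- function(graph) {
  g <- as_igraph(graph)
  D <- igraph::distances(g, weights = NA)
  d <- D[row(D) != col(D)]
  finite <- is.finite(d)
  tab <- table(d[finite])
  census <- data.frame(
    length = as.integer(names(tab)),
    n_pairs = as.integer(tab)
  )
  census$pct_connected <- 100 * census$n_pairs / sum(census$n_pairs)
  list(
    census = census,
    n_connected_pairs = sum(finite),
    n_disconnected_pairs = sum(!finite),
    n_ordered_pairs = length(d)
  )
}

#' Degree-distribution histogram
#'
#' @param metrics output of [weighted_degree()].
#' @param binning `"log"` (log-spaced bins of the weighted degree, zero
#'   degrees reported separately) or `"linear"`.
#' @param bin_width linear bin width (default 1).
#' @param log_base log-binning base (default 2).
#' @param value which column to bin, `"k"` (weighted) or `"degree"`.
#' @return data.frame with `bin_lo`, `bin_hi` (half-open `[lo, hi)` bins),
#'   `mid`, `count`; attribute `n_zero` counts zero-degree nodes.
#' @export
degree_histogram <- function(metrics, binning = c("log", "linear"),
                             bin_width = 1, log_base = 2, value = "k") {
  binning <- match.arg(binning)
  v <- metrics[[value]]
  n_zero <- sum(v == 0)
  v <- v[v > 0]
  if (length(v) == 0) stop("no nonzero degrees to bin")
  if (binning == "linear") {
    breaks <- seq(0, max(v) + bin_width, by = bin_width)
  } else {
    top <- ceiling(log(max(v), log_base)) + 1
    bottom <- floor(log(min(v), log_base))
    breaks <- log_base^(bottom:top)
  }
  cut_idx <- findInterval(v, breaks, rightmost.closed = FALSE)
  counts <- tabulate(cut_idx, nbins = length(breaks) - 1)
  out <- data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = counts
  )
  out$mid <- sqrt(out$bin_lo * out$bin_hi)
  if (binning == "linear") out$mid <- (out$bin_lo + out$bin_hi) / 2
  attr(out, "n_zero") <- n_zero
  out
}

#' Fit a log-log slope to a degree histogram
#'
#' Least-squares slope of log(frequency density) against log(degree) over
#' non-empty bins; a quick power-law exponent estimate (no hypothesis test).
#'
#' @param hist output of [degree_histogram()] with log binning.
#' @return the fitted slope (for a power law `p(k) ~ k^-a`, about `-a`).
#' @export
degree_loglog_slope <- function(hist) {
  keep <- hist$count > 0
  dens <- hist$count[keep] / (hist$bin_hi[keep] - hist$bin_lo[keep])
  stats::coef(stats::lm(log(dens) ~ log(hist$mid[keep])))[[2]]
}
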