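#' Geodesic (hop-count) distance matrix
#'
#' Breadth-first shortest path lengths over the unweighted topology;
#' `Inf` marks disconnected pairs.
#'
#' @param graph a [weighted_graph()].
#' @return symmetric numeric matrix with zero diagonal, dimnames = node IDs.
#' @export
graph_distances <- function(graph) {
  g <- as_igraph(graph)
  D <- igraph::distances(g, weights = NA)
  dimnames(D) <- list(graph$ids, graph$ids)
  D
}

#' Spectral distance embedding (classical MDS of geodesics)
#'
#' Lays the graph out so that inter-point Euclidean distances approximate
#' the graph-theoretic distances: double-center `-D^2/2`, take the `dims`
#' leading eigenpairs with positive eigenvalues, and scale each eigenvector
#' by the square root of its eigenvalue. The layout is computed on the
#' largest connected component; nodes outside it are placed on a display
#' ring at 1.2x the embedding radius and flagged. Residual stress
#' `sum (||x_i - x_j|| - D_ij)^2` over embedded pairs is reported.
#'
#' Eigenvector signs are fixed (largest-magnitude coordinate positive) so
#' repeated runs give identical output.
#'
#' @param D distance matrix from [graph_distances()] (or any symmetric
#'   dissimilarity with `Inf` for unreachable pairs).
#' @param dims 2 or 3.
#' @return list with `coords` (data.frame `node`, `X1..Xdims`,
#'   `in_embedding`), `stress`, `eigenvalues` and `dims_used`.
#' @export
sde_layout <- function(D, dims = 2) {
  stopifnot(dims %in% c(2, 3))
  n <- nrow(D)
  ids <- if (!is.null(rownames(D))) as.integer(rownames(D)) else seq_len(n)
  # largest finite block = largest component
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cc <- cc + 1L
      comp[is.finite(D[i, ])] <- cc
      comp[i] <- cc
    }
  }
  main <- which(comp == which.max(tabulate(comp)))
  Ds <- D[main, main, drop = FALSE]

  B <- -0.5 * Ds^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))
  es <- eigen(B, symmetric = TRUE)
  pos <- which(es$values > 1e-9)
  d_used <- min(dims, length(pos))
  if (d_used < dims) {
    warning("only ", d_used, " positive eigenvalue(s); reduced-dimension layout")
  }
  X <- es$vectors[, pos[seq_len(d_used)], drop = FALSE] %*%
    diag(sqrt(es$values[pos[seq_len(d_used)]]), d_used)
  # deterministic sign: largest-magnitude coordinate of each axis positive
  for (k in seq_len(d_used)) {
    jmax <- which.max(abs(X[, k]))
    if (X[jmax, k] < 0) X[, k] <- -X[, k]
  }
  stress <- sum((as.matrix(stats::dist(X)) - Ds)^2) / 2

  coords <- matrix(NA_real_, n, dims)
  coords[main, seq_len(d_used)] <- X
  if (d_used < dims) coords[main, (d_used + 1):dims] <- 0
  outside <- setdiff(seq_len(n), main)
  if (length(outside) > 0) {
    r <- 1.2 * max(sqrt(rowSums(X^2)), 1)
    ang <- 2 * pi * (seq_along(outside) - 1) / length(outside)
    ring <- cbind(r * cos(ang), r * sin(ang))
    coords[outside, 1:2] <- ring
    if (dims == 3) coords[outside, 3] <- 0
  }
  out <- data.frame(node = ids, coords)
  names(out)[-1] <- paste0("X", seq_len(dims))
  out$in_embedding <- seq_len(n) %in% main
  list(coords = out,
       stress = stress,
       eigenvalues = es$values,
       dims_used = d_used)
}

#' Anatomically layered layout
#'
#' One axis is a class-assigned layer depth (bipolar cells innermost at
#' 0.1 through ganglion cells at 0.9, mirroring the anatomical ordering of
#' the inner plexiform layer); the remaining axes carry the soma plane
#' coordinates.
#'
#' @param catalog a [cell_catalog][load_cell_catalog()].
#' @param depth_by_class named numeric vector mapping every broad cell
#'   class present to a layer depth.
#' @param plane_axes catalog columns used for the in-plane axes.
#' @return data.frame `node`, `depth`, `u`, `v`.
#' @export
anatomical_layout <- function(catalog,
                              depth_by_class = c(cBC = 0.1, rBC = 0.1,
                                                 NFac = 0.5, WFac = 0.5,
                                                 other = 0.3, GC = 0.9),
                              plane_axes = c("x", "y")) {
  cls <- catalog$cell_class
  unmapped <- setdiff(unique(cls), names(depth_by_class))
  if (length(unmapped) > 0) {
    stop("no layer depth configured for class(es): ",
         paste(unmapped, collapse = ", "))
  }
  data.frame(
    node = catalog$id,
    depth = unname(depth_by_class[cls]),
    u = catalog[[plane_axes[1]]],
    v = catalog[[plane_axes[2]]]
  )
}

#' Strong-link subgraph around focus neurons
#'
#' Keeps exactly the links incident to a focus neuron whose weight strictly
#' exceeds `weight_min`, together with their endpoint nodes. Links between
#' two non-focus endpoints are not included.
#'
#' @param graph a [weighted_graph()].
#' @param focus_nodes neuron IDs of interest.
#' @param weight_min strict lower weight bound (captions like "(>10)" mean
#'   `weight_min = 10`).
#' @return a [weighted_graph()] over the retained nodes, with attribute
#'   `n_links`.
#' @export
strong_link_subgraph <- function(graph, focus_nodes, weight_min = 10) {
  fidx <- match(focus_nodes, graph$ids)
  if (anyNA(fidx)) {
    stop("unknown focus node id(s): ",
         paste(focus_nodes[is.na(fidx)], collapse = ", "))
  }
  A <- graph$A
  keep <- matrix(FALSE, nrow(A), ncol(A))
  keep[fidx, ] <- keep[fidx, ] | (A[fidx, , drop = FALSE] > weight_min)
  keep <- keep | t(keep)
  nodes <- sort(unique(c(fidx, which(colSums(keep) > 0))))
  A_sub <- matrix(0, length(nodes), length(nodes))
  A_sub[keep[nodes, nodes]] <- A[nodes, nodes][keep[nodes, nodes]]
  g <- weighted_graph(A_sub, ids = graph$ids[nodes], threshold = graph$threshold)
  attr(g, "n_links") <- sum(A_sub[upper.tri(A_sub)] > 0)
  attr(g, "focus") <- graph$ids[fidx]
  g
}

#' Render a module-colored network view
#'
#' Static figure of a (sub)graph on given coordinates: links as segments,
#' nodes shaped by cell class and colored by module, with optional module
#' convex hulls and centroids. Deterministic for fixed inputs.
#'
#' @param coords data.frame with `node` and two coordinate columns (the
#'   first two non-`node` numeric columns are used).
#' @param subgraph a [weighted_graph()] over (a subset of) the coords nodes.
#' @param partition optional [node_partition()] for module colors.
#' @param catalog optional catalog for class shapes.
#' @param file output path (`.png` or `.pdf`).
#' @param show_hulls draw convex hulls per module (needs >= 3 located
#'   members).
#' @param width,height,dpi figure size (inches) and resolution.
#' @return `file`, invisibly. Nodes without coordinates are omitted with a
#'   warning.
#' @export
render_view <- function(coords, subgraph, partition = NULL, catalog = NULL,
                        file = "network_view.png", show_hulls = FALSE,
                        width = 7, height = 6, dpi = 150) {
  axes <- setdiff(names(coords), c("node", "in_embedding"))[1:2]
  pts <- data.frame(node = coords$node,
                    u = coords[[axes[1]]], v = coords[[axes[2]]])
  pts <- pts[pts$node %in% subgraph$ids, , drop = FALSE]
  miss <- setdiff(subgraph$ids, pts$node[!is.na(pts$u)])
  if (length(miss) > 0) {
    warning("omitting ", length(miss), " node(s) without coordinates")
    pts <- pts[!is.na(pts$u), , drop = FALSE]
  }
  pts$module <- if (!is.null(partition)) {
    factor(partition$membership[as.character(pts$node)])
  } else factor(1)
  pts$class <- if (!is.null(catalog)) {
    cell_class_of(catalog, pts$node, prefer_subclass = FALSE)
  } else "node"

  ed <- graph_edges(subgraph)
  ed <- ed[ed$i %in% pts$node & ed$j %in% pts$node, , drop = FALSE]
  seg <- data.frame(
    u = pts$u[match(ed$i, pts$node)], v = pts$v[match(ed$i, pts$node)],
    u2 = pts$u[match(ed$j, pts$node)], v2 = pts$v[match(ed$j, pts$node)],
    weight = ed$weight
  )

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$u, y = .data$v, xend = .data$u2, yend = .data$v2,
                   linewidth = .data$weight),
      color = "grey60", alpha = 0.5
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 1.2), guide = "none") +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$u, y = .data$v, color = .data$module,
                   shape = .data$class),
      size = 2
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = axes[1], y = axes[2])

  if (show_hulls && !is.null(partition)) {
    hull_rows <- do.call(rbind, lapply(split(pts, pts$module), function(d) {
      if (nrow(d) < 3) return(NULL)
      h <- grDevices::chull(d$u, d$v)
      d[h, c("u", "v", "module")]
    }))
    if (!is.null(hull_rows)) {
      p <- p + ggplot2::geom_polygon(
        data = hull_rows,
        ggplot2::aes(x = .data$u, y = .data$v, group = .data$module,
                     color = .data$module),
        fill = NA, linetype = 2
      )
    }
  }
  ggplot2::ggsave(file, p, width = width, height = height, dpi = dpi)
  invisible(file)
}
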