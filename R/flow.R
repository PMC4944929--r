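#' Stationary visit rates of the random walk
#'
#' For an undirected weighted walk the stationary distribution is
#' strength-proportional: `p_i = k_i / sum_j k_j`. Zero-degree nodes are
#' never visited and get `p_i = 0` (downstream they are carried as
#' singleton modules with zero flow).
#'
#' @param graph a [weighted_graph()].
#' @return named numeric vector of visit rates, names = node IDs; sums to 1
#'   over linked nodes.
#' @export
stationary_flow <- function(graph) {
  k <- rowSums(graph$A)
  if (all(k == 0)) stop("graph has no links: stationary flow undefined")
  p <- k / sum(k)
  names(p) <- graph$ids
  p
}

plogp <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Module assignment container
#'
#' @param membership integer module labels (>= 1), named by node ID; labels
#'   must be contiguous from 1.
#' @param method name of the producing method.
#' @param seed,trials search metadata (optional).
#' @return an object of class `node_partition`.
#' @export
node_partition <- function(membership, method = "manual",
                           seed = NA_integer_, trials = NA_integer_) {
  membership <- stats::setNames(as.integer(membership), names(membership))
  if (anyNA(membership)) stop("membership labels must be non-missing integers")
  labs <- sort(unique(membership))
  if (!identical(labs, seq_along(labs))) {
    # relabel to contiguous 1..M preserving order of first appearance of the
    # sorted labels
    membership[] <- match(membership, labs)
  }
  structure(
    list(membership = membership, method = method, seed = seed, trials = trials),
    class = "node_partition"
  )
}

#' @export
print.node_partition <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("<node_partition> %d nodes in %d modules (method: %s)\n",
              length(x$membership), length(sizes), x$method))
  cat("module sizes:", paste(utils::head(sort(as.integer(sizes), decreasing = TRUE), 12),
                             collapse = ", "),
      if (length(sizes) > 12) "..." else "", "\n")
  invisible(x)
}

# internal: membership vector aligned to graph$ids (error if nodes missing)
aligned_membership <- function(graph, partition) {
  m <- partition$membership
  idx <- match(as.character(graph$ids), names(m))
  if (anyNA(idx)) {
    stop("partition is missing node(s): ",
         paste(utils::head(graph$ids[is.na(idx)], 10), collapse = ", "))
  }
  as.integer(m[idx])
}

#' Per-node and per-module flow bookkeeping for a partition
#'
#' Computes the quantities entering the two-level map equation: node visit
#' rates `p_i`, per-module internal flow `p_m` (sum of member visit rates),
#' per-module exit probability `q_m` (stationary flow along links leaving
#' the module), total exit flow `q`, and the codelength in bits.
#'
#' @param graph a [weighted_graph()].
#' @param partition a [node_partition()] covering all linked nodes.
#' @return list with `p` (named vector), `modules` (data.frame `module`,
#'   `p_internal`, `q_exit`, `n_members`), `q_total` and `codelength`.
#' @export
flow_summary <- function(graph, partition) {
  p <- stationary_flow(graph)
  m <- aligned_membership(graph, partition)
  two_w <- sum(graph$A)
  n_mod <- max(m)

  p_mod <- as.numeric(rowsum(p, m, reorder = TRUE))
  # exit flow: weight of links with endpoints in different modules, per module
  ind <- outer(m, sort(unique(m)), "==") * 1     # N x M indicator
  W_mm <- t(ind) %*% graph$A %*% ind             # module-to-module weight
  q_mod <- (rowSums(W_mm) - diag(W_mm)) / two_w
  q_tot <- sum(q_mod)

  L <- plogp(q_tot) - 2 * sum(plogp(q_mod)) +
    sum(plogp(p_mod + q_mod)) - sum(plogp(p))

  list(
    p = p,
    modules = data.frame(
      module = seq_len(n_mod),
      p_internal = p_mod,
      q_exit = q_mod,
      n_members = as.integer(table(factor(m, levels = seq_len(n_mod))))
    ),
    q_total = q_tot,
    codelength = L
  )
}

#' Map-equation codelength of a partition
#'
#' Two-level map equation in bits per random-walk step:
#' `L = q H(Q) + sum_m (p_m + q_m) H(P_m)`, where `q_m` is the stationary
#' flow out of module `m`, `H(Q)` the entropy of the normalized exit flows
#' and `H(P_m)` the entropy of module `m`'s exit and within-module visit
#' rates. A single-module partition reduces to the entropy of the visit
#' rates, `-sum_i p_i log2 p_i`. All logarithms are base 2.
#'
#' @inheritParams flow_summary
#' @return codelength in bits.
#' @export
map_codelength <- function(graph, partition) {
  flow_summary(graph, partition)$codelength
}

#' Flow-based module detection (map-equation minimization)
#'
#' Seeks the partition minimizing the two-level map-equation codelength by
#' a greedy node-move + module-aggregation search (Louvain-style) with
#' seeded random restarts; the best of `trials` restarts is returned.
#' Zero-degree nodes carry no flow and are appended as singleton modules.
#' Modules are relabeled in decreasing order of total internal flow (ties:
#' smallest member ID first).
#'
#' @param graph a [weighted_graph()].
#' @param seed integer seed; the search is reproducible bit-for-bit given
#'   `(graph, seed, trials)`.
#' @param trials number of seeded restarts (>= 1).
#' @return list with `partition` (a [node_partition()]), `flow` (the
#'   [flow_summary()] of the returned partition) and `codelength`.
#' @export
infomap_partition <- function(graph, seed = 1L, trials = 10L) {
  stopifnot(trials >= 1)
  k <- rowSums(graph$A)
  linked <- which(k > 0)
  if (length(linked) == 0) stop("graph has no links")

  sub <- graph$A[linked, linked, drop = FALSE]
  idx <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
  res <- infomap_core(
    n = length(linked),
    ei = idx[, 1] - 1L, ej = idx[, 2] - 1L,
    w = sub[idx],
    trials = as.integer(trials), seed = as.integer(seed)
  )
  memb_linked <- res$membership + 1L

  # order modules by total flow (desc), ties by smallest member id
  p <- stationary_flow(graph)[linked]
  flow_by_mod <- as.numeric(rowsum(p, memb_linked))
  min_id <- tapply(graph$ids[linked], memb_linked, min)
  ord <- order(-flow_by_mod, min_id)
  relabel <- integer(length(ord)); relabel[ord] <- seq_along(ord)
  memb_linked <- relabel[memb_linked]

  membership <- integer(length(graph$ids))
  membership[linked] <- memb_linked
  # zero-degree nodes -> singleton modules after the flow-carrying ones
  zero <- which(k == 0)
  if (length(zero) > 0) {
    membership[zero] <- max(memb_linked) + seq_along(zero)
  }
  names(membership) <- graph$ids
  part <- node_partition(membership, method = "infomap",
                         seed = seed, trials = trials)
  fs <- flow_summary(graph, part)
  list(partition = part, flow = fs, codelength = fs$codelength)
}

#' Table-1-style module summary
#'
#' Per module: total internal signal flow, member count, the leading member
#' cell classes, sorted by flow in decreasing order.
#'
#' @param flow a [flow_summary()].
#' @param partition the matching [node_partition()].
#' @param catalog optional [cell_catalog][load_cell_catalog()] for class
#'   labels.
#' @param nontrivial_min_members,nontrivial_min_flow a module is flagged
#'   non-trivial when it has more than `nontrivial_min_members` members or
#'   more than `nontrivial_min_flow` of the total flow.
#' @return data.frame with columns `module`, `flow`, `n_members`,
#'   `key_classes`, `nontrivial`.
#' @export
module_flow_table <- function(flow, partition, catalog = NULL,
                              nontrivial_min_members = 15,
                              nontrivial_min_flow = 0.01) {
  m <- partition$membership
  tab <- flow$modules
  key <- rep(NA_character_, nrow(tab))
  if (!is.null(catalog)) {
    cls <- cell_class_of(catalog, as.integer(names(m)))
    for (mm in tab$module) {
      cnt <- sort(table(cls[m == mm]), decreasing = TRUE)
      key[mm] <- paste(utils::head(names(cnt), 2), collapse = ", ")
    }
  }
  out <- data.frame(
    module = tab$module,
    flow = tab$p_internal,
    n_members = tab$n_members,
    key_classes = key
  )
  out <- out[order(-out$flow, out$module), , drop = FALSE]
  out$nontrivial <- out$n_members > nontrivial_min_members |
    out$flow > nontrivial_min_flow
  rownames(out) <- NULL
  out
}

#' Write / read a module-membership file
#'
#' Plain-text dialect of the supplementary membership lists: one
#' `node_id module_id` pair per line, whitespace separated.
#'
#' @param partition a [node_partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(partition, path) {
  m <- partition$membership
  writeLines(paste(names(m), m), path)
  invisible(path)
}

#' @rdname write_membership
#' @param method method tag recorded on the partition read back.
#' @return `read_membership()` returns a [node_partition()].
#' @export
read_membership <- function(path, method = "file") {
  tab <- utils::read.table(path, col.names = c("node", "module"))
  node_partition(stats::setNames(tab$module, tab$node), method = method)
}
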