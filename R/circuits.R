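#' Default Off/On assignment of cone bipolar subtypes
#'
#' Off-stratifying cone bipolar types 1-4 versus On types 5-9 and XBC,
#' following the standard inner-plexiform-layer convention. Used to tally
#' a focus neuron's Off- vs On-type cBC inputs; it is configuration, not
#' code, and can be overridden per analysis.
#'
#' @return named character vector, subtype -> "Off"/"On".
#' @export
default_off_on_map <- function() {
  c("cBC-1" = "Off", "cBC-2" = "Off", "cBC-3A" = "Off", "cBC-3B" = "Off",
    "cBC-4" = "Off",
    "cBC-5A" = "On", "cBC-5R" = "On", "cBC-5X" = "On", "cBC-6" = "On",
    "cBC-7" = "On", "cBC-8" = "On", "cBC-9" = "On", "XBC" = "On")
}

#' Circuit report for a focus neuron
#'
#' Partitions the focus neuron's adjacency row by partner cell class:
#' strong links (weight > `strong_min`, sorted by weight descending),
#' candidate feedback links (bipolar partners with weight <=
#' `feedback_max`; weak amacrine-to-bipolar links are the anatomically
#' plausible gain-control pathway), and tallies of Off- vs On-type cone
#' bipolar inputs, rod bipolar inputs, amacrine and ganglion-cell links.
#'
#' @param graph a [weighted_graph()].
#' @param catalog a [cell_catalog][load_cell_catalog()].
#' @param focus focus neuron ID.
#' @param strong_min strict weight threshold for strong links (default 10).
#' @param feedback_max inclusive weight ceiling for feedback candidates
#'   (default 2).
#' @param off_on_map named map of cBC subtype -> "Off"/"On"
#'   ([default_off_on_map()]). Unmapped subtypes are counted as
#'   unclassified with a warning.
#' @return object of class `circuit_report`: list with `focus` (id, class,
#'   subtype), `partners` (all linked partners), `strong`, `feedback`,
#'   and `tallies`.
#' @export
circuit_report <- function(graph, catalog, focus, strong_min = 10,
                           feedback_max = 2, off_on_map = default_off_on_map()) {
  fi <- match(focus, graph$ids)
  if (is.na(fi)) stop("focus neuron ", focus, " is not in the graph")
  row <- graph$A[fi, ]
  partner_idx <- which(row > 0)
  partners <- data.frame(
    partner = graph$ids[partner_idx],
    weight = unname(row[partner_idx])
  )
  partners$class <- cell_class_of(catalog, partners$partner)
  partners$broad <- cell_class_of(catalog, partners$partner,
                                  prefer_subclass = FALSE)
  partners$subtype <- catalog$subtype[match(partners$partner, catalog$id)]
  partners <- partners[order(-partners$weight, partners$partner), , drop = FALSE]
  rownames(partners) <- NULL

  strong <- partners[partners$weight > strong_min, , drop = FALSE]
  feedback <- partners[partners$broad %in% c("cBC", "rBC") &
                         partners$weight <= feedback_max, , drop = FALSE]

  cbc <- partners[partners$broad == "cBC", , drop = FALSE]
  oo <- unname(off_on_map[cbc$subtype])
  n_unclassified <- sum(!is.na(cbc$subtype) & is.na(oo)) +
    sum(is.na(cbc$subtype))
  if (any(!is.na(cbc$subtype) & is.na(oo))) {
    warning("unmapped cBC subtype(s): ",
            paste(unique(cbc$subtype[!is.na(cbc$subtype) & is.na(oo)]),
                  collapse = ", "))
  }
  tallies <- c(
    cbc_off = sum(oo == "Off", na.rm = TRUE),
    cbc_on = sum(oo == "On", na.rm = TRUE),
    cbc_unclassified = n_unclassified,
    rbc = sum(partners$broad == "rBC"),
    ac = sum(partners$broad %in% c("NFac", "WFac")),
    gc = sum(partners$broad == "GC")
  )

  structure(list(
    focus = list(id = focus,
                 class = cell_class_of(catalog, focus),
                 subtype = catalog$subtype[match(focus, catalog$id)]),
    partners = partners,
    strong = strong,
    feedback = feedback,
    tallies = tallies,
    strong_min = strong_min,
    feedback_max = feedback_max
  ), class = "circuit_report")
}

#' @export
print.circuit_report <- function(x, ...) {
  cat(sprintf("<circuit_report> focus neuron %d (%s%s)\n",
              x$focus$id, x$focus$class,
              if (!is.na(x$focus$subtype)) paste0(", ", x$focus$subtype) else ""))
  cat(sprintf("  %d partners; %d strong (weight > %g); %d feedback candidates (BC, weight <= %g)\n",
              nrow(x$partners), nrow(x$strong), x$strong_min,
              nrow(x$feedback), x$feedback_max))
  if (nrow(x$strong) > 0) {
    cat("  strongest links (weight, rounded for display):\n")
    top <- utils::head(x$strong, 8)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    -> %d (%s%s)  weight %d\n", top$partner[i], top$class[i],
                  if (!is.na(top$subtype[i])) paste0(", ", top$subtype[i]) else "",
                  round(top$weight[i])))
    }
  }
  cat(sprintf("  cBC inputs: %d Off, %d On (%d unclassified); rBC %d; ac %d; GC %d\n",
              x$tallies["cbc_off"], x$tallies["cbc_on"],
              x$tallies["cbc_unclassified"], x$tallies["rbc"],
              x$tallies["ac"], x$tallies["gc"]))
  invisible(x)
}

#' Cross-measure node ranking table
#'
#' Side-by-side top-k node IDs ranked by signal flow, node betweenness and
#' weighted degree, with pairwise overlap counts. Ties break toward the
#' smaller ID, deterministically.
#'
#' @param flow named visit-rate vector ([stationary_flow()]) or a
#'   [flow_summary()].
#' @param metrics data.frame with `node`, `k` and `nbc` columns (e.g.
#'   [weighted_degree()] merged with [betweenness_centrality()] nodes).
#' @param top_k list length (default 10).
#' @return list with `table` (data.frame `rank`, `by_flow`, `by_nbc`,
#'   `by_degree`) and `overlap` (named vector of pairwise and three-way
#'   intersection sizes).
#' @export
rank_nodes <- function(flow, metrics, top_k = 10) {
  p <- if (is.list(flow) && !is.null(flow$p)) flow$p else flow
  ids_flow <- as.integer(names(p))
  stopifnot(all(c("node", "k", "nbc") %in% names(metrics)))
  common <- intersect(ids_flow, metrics$node)
  p <- p[as.character(common)]
  k <- metrics$k[match(common, metrics$node)]
  nbc <- metrics$nbc[match(common, metrics$node)]

  top_by <- function(v) common[order(-v, common)][seq_len(min(top_k, length(common)))]
  t_flow <- top_by(p)
  t_nbc <- top_by(nbc)
  t_k <- top_by(k)
  list(
    table = data.frame(rank = seq_along(t_flow), by_flow = t_flow,
                       by_nbc = t_nbc, by_degree = t_k),
    overlap = c(
      flow_nbc = length(intersect(t_flow, t_nbc)),
      flow_degree = length(intersect(t_flow, t_k)),
      nbc_degree = length(intersect(t_nbc, t_k)),
      all_three = length(Reduce(intersect, list(t_flow, t_nbc, t_k)))
    )
  )
}
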