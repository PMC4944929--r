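#' Classify neurons as core or edge of the sample plane
#'
#' A neuron is `edge` when its lateral (in-plane) soma coordinate lies
#' within `margin` of any of the four plane boundaries, `core` otherwise,
#' and `unknown` when it has no coordinates. Only in-plane coordinates are
#' used; depth never enters.
#'
#' @param catalog a [cell_catalog][load_cell_catalog()] with soma
#'   coordinates.
#' @param margin edge margin in um (default 10).
#' @param plane_bounds lengths `(Lx, Ly)` of the analysis plane in um.
#' @param plane_axes which two catalog coordinate columns span the plane.
#' @return data.frame with columns `id`, `zone` (factor core/edge/unknown);
#'   attributes `margin` and `plane_bounds`.
#' @export
classify_edge_core <- function(catalog, margin = 10, plane_bounds = c(80, 114),
                               plane_axes = c("x", "y")) {
  if (margin <= 0 || margin >= min(plane_bounds) / 2) {
    stop("`margin` must be positive and less than half the smallest plane extent")
  }
  u <- catalog[[plane_axes[1]]]
  v <- catalog[[plane_axes[2]]]
  zone <- rep("unknown", nrow(catalog))
  has <- !is.na(u) & !is.na(v)
  near_edge <- has & (u < margin | u > plane_bounds[1] - margin |
                        v < margin | v > plane_bounds[2] - margin)
  zone[has] <- "core"
  zone[near_edge] <- "edge"
  out <- data.frame(id = catalog$id,
                    zone = factor(zone, levels = c("core", "edge", "unknown")))
  attr(out, "margin") <- margin
  attr(out, "plane_bounds") <- plane_bounds
  out
}

#' Zone-mean network measures (edge-artifact report)
#'
#' Mean weighted degree (and mean node betweenness when present) for core
#' nodes, edge nodes and the whole sample, with the edge deficit expressed
#' as a percentage of the core mean. Quantifies the sample-excision
#' artifact: neurons near the cut boundary lost links to partners outside
#' the excised volume.
#'
#' @param metrics data.frame with `node` plus measure columns (`k`, and
#'   optionally `nbc`), e.g. [weighted_degree()] output.
#' @param labels output of [classify_edge_core()].
#' @return list with `table` (rows core/edge/all; mean of each measure and
#'   `n`) and `deficit_pct` (named vector, `100 * (core - edge) / core`).
#' @export
edge_effect_report <- function(metrics, labels) {
  z <- labels$zone[match(metrics$node, labels$id)]
  measures <- intersect(c("k", "nbc", "degree"), names(metrics))
  rows <- list(core = which(z == "core"), edge = which(z == "edge"),
               all = which(z != "unknown"))
  tab <- data.frame(zone = names(rows),
                    n = vapply(rows, length, 0L))
  for (ms in measures) {
    tab[[paste0("mean_", ms)]] <-
      vapply(rows, function(i) if (length(i)) mean(metrics[[ms]][i]) else NA_real_, 0)
  }
  deficit <- vapply(measures, function(ms) {
    co <- tab[[paste0("mean_", ms)]][tab$zone == "core"]
    ed <- tab[[paste0("mean_", ms)]][tab$zone == "edge"]
    if (is.na(co) || co == 0) NA_real_ else 100 * (co - ed) / co
  }, 0)
  list(table = tab, deficit_pct = deficit)
}

# --- convex polygon helpers (2D) ---------------------------------------

# signed shoelace area of an (ordered) polygon matrix [x, y]
polygon_area <- function(P) {
  n <- nrow(P)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2])) / 2
}

polygon_centroid <- function(P) {
  n <- nrow(P)
  i2 <- c(2:n, 1)
  cr <- P[, 1] * P[i2, 2] - P[i2, 1] * P[, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(P))
  c(sum((P[, 1] + P[i2, 1]) * cr) / (6 * a),
    sum((P[, 2] + P[i2, 2]) * cr) / (6 * a))
}

# Sutherland-Hodgman clip of (convex) polygon P against convex clip polygon C;
# both counter-clockwise. Returns the intersection polygon (possibly 0 rows).
# Hand-rolled because no installed package offers polygon clipping.
clip_convex <- function(P, C) {
  n_c <- nrow(C)
  out <- P
  for (k in seq_len(n_c)) {
    if (nrow(out) == 0) return(out)
    a <- C[k, ]
    b <- C[if (k == n_c) 1 else k + 1, ]
    # inside = left of directed edge a->b
    side <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n_p <- nrow(inp)
    for (i in seq_len(n_p)) {
      p <- inp[i, ]
      q <- inp[if (i == n_p) 1 else i + 1, ]
      sp <- side(p); sq <- side(q)
      if (sp >= -1e-12) out <- rbind(out, p)
      if ((sp > 1e-12 && sq < -1e-12) || (sp < -1e-12 && sq > 1e-12)) {
        t <- sp / (sp - sq)
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  out
}

# counter-clockwise convex hull of points [x, y] (grDevices::chull is clockwise)
ccw_hull <- function(pts) {
  h <- grDevices::chull(pts)
  P <- pts[rev(h), , drop = FALSE]
  P
}

#' Module mosaic geometry in the retinal plane
#'
#' For each module (optionally restricted to one cell class, e.g. the cone
#' bipolar cells of the mosaic figure) with at least 3 located members:
#' the 2D convex hull of member somata, its area and centroid, plus all
#' pairwise hull-overlap areas and a tiling score (total pairwise overlap
#' area / total hull area; a clean mosaic scores near 0).
#'
#' @param catalog a [cell_catalog][load_cell_catalog()].
#' @param partition a [node_partition()].
#' @param cell_class optional class label filter (see [cell_class_of()];
#'   matched against the broad class).
#' @param plane_axes the two coordinate columns spanning the plane.
#' @param min_members modules with fewer located members are reported as
#'   degenerate (no hull).
#' @return list with `modules` (data.frame `module`, `n_members`,
#'   `hull_area`, `centroid_u`, `centroid_v`, `degenerate`), `hulls` (named
#'   list of hull vertex matrices), `overlaps` (data.frame `module_a`,
#'   `module_b`, `area`) and `tiling_score`.
#' @export
module_geometry <- function(catalog, partition, cell_class = NULL,
                            plane_axes = c("x", "y"), min_members = 3) {
  m <- partition$membership
  ids <- as.integer(names(m))
  keep <- rep(TRUE, length(ids))
  if (!is.null(cell_class)) {
    cls <- cell_class_of(catalog, ids, prefer_subclass = FALSE)
    keep <- keep & cls %in% cell_class
  }
  u <- catalog[[plane_axes[1]]][match(ids, catalog$id)]
  v <- catalog[[plane_axes[2]]][match(ids, catalog$id)]
  keep <- keep & !is.na(u) & !is.na(v)

  mods <- sort(unique(m[keep]))
  hulls <- list()
  rows <- list()
  for (mm in mods) {
    sel <- keep & m == mm
    pts <- cbind(u[sel], v[sel])
    if (nrow(pts) < min_members || nrow(unique(pts)) < 3) {
      rows[[length(rows) + 1]] <- data.frame(
        module = mm, n_members = nrow(pts), hull_area = NA_real_,
        centroid_u = mean(pts[, 1]), centroid_v = mean(pts[, 2]),
        degenerate = TRUE
      )
      next
    }
    H <- ccw_hull(pts)
    cen <- polygon_centroid(H)
    hulls[[as.character(mm)]] <- H
    rows[[length(rows) + 1]] <- data.frame(
      module = mm, n_members = nrow(pts), hull_area = polygon_area(H),
      centroid_u = cen[1], centroid_v = cen[2], degenerate = FALSE
    )
  }
  modules <- do.call(rbind, rows)

  hull_mods <- names(hulls)
  overlaps <- data.frame(module_a = integer(0), module_b = integer(0),
                         area = numeric(0))
  if (length(hull_mods) >= 2) {
    combs <- utils::combn(hull_mods, 2)
    for (ci in seq_len(ncol(combs))) {
      inter <- clip_convex(hulls[[combs[1, ci]]], hulls[[combs[2, ci]]])
      a <- if (nrow(inter) >= 3) polygon_area(inter) else 0
      overlaps <- rbind(overlaps, data.frame(
        module_a = as.integer(combs[1, ci]),
        module_b = as.integer(combs[2, ci]), area = a
      ))
    }
  }
  total_hull <- sum(modules$hull_area, na.rm = TRUE)
  tiling <- if (total_hull > 0) sum(overlaps$area) / total_hull else NA_real_
  list(modules = modules, hulls = hulls, overlaps = overlaps,
       tiling_score = tiling)
}
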