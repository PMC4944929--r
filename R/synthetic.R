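#' Parameters for the retina-like sample generator
#'
#' Defaults emulate the 0.1 mm retina sample the pipeline targets: 950
#' neurons of six classes (plus starburst subranges and 173 glia) placed
#' uniformly in a 132 x 114 x 80 um box, spatially planted modules in the
#' retinal plane, laterally decaying multi-contact rates, lognormal contact
#' areas, a 14% reversed-duplicate listing rate, and excision of contacts
#' whose centroid leaves the box.
#'
#' Contact counts per unordered pair are Poisson with rate
#' `contact_rate * exp(-d / lambda) * rho^[same module]`, `d` the lateral
#' soma distance. The lognormal area parameters are calibrated so that
#' about 41% of contacts reach the 0.08 um^2 synapse-probability threshold.
#'
#' @param box sample box dimensions (um), lateral x, lateral y, depth z.
#' @param ranges cell-class ID ranges ([default_cell_ranges()] layout);
#'   class counts are derived from them.
#' @param n_glia number of glia cells (IDs appended after the neurons;
#'   their contacts are flagged for the ingest filter to drop).
#' @param glia_rate_factor multiplier on the contact rate for pairs
#'   involving glia.
#' @param n_modules number of planted modules M.
#' @param module_centers optional M x 2 matrix of plane centers (um);
#'   drawn with a minimum-separation rule when `NULL`.
#' @param rho within-module / between-module contact-rate ratio (>= 1).
#' @param lambda lateral distance decay scale (um).
#' @param contact_rate Poisson base rate: mean contacts for a same-plane
#'   between-module pair at distance 0.
#' @param area_meanlog,area_sdlog lognormal contact-area parameters
#'   (log um^2).
#' @param dup_frac probability that a contact is listed a second time in
#'   reversed order (the over-counting artifact), per contact.
#' @param contact_jitter isotropic sd (um) of the contact centroid around
#'   the soma midpoint.
#' @return a validated `generator_params` list.
#' @export
generator_params <- function(box = c(132, 114, 80),
                             ranges = default_cell_ranges(),
                             n_glia = 173,
                             glia_rate_factor = 0.1,
                             n_modules = 10,
                             module_centers = NULL,
                             rho = 8,
                             lambda = 10,
                             contact_rate = 1.0,
                             area_meanlog = -2.753,
                             area_sdlog = 1.0,
                             dup_frac = 0.14,
                             contact_jitter = 2) {
  stopifnot(length(box) == 3, all(box > 0))
  if (n_modules < 1) stop("`n_modules` must be >= 1")
  if (lambda <= 0) stop("`lambda` must be positive")
  if (rho < 1) stop("`rho` must be >= 1")
  if (dup_frac < 0 || dup_frac > 1) stop("`dup_frac` must be in [0, 1]")
  if (n_glia < 0 || contact_rate <= 0) stop("degenerate generator parameters")
  structure(list(
    box = box, ranges = ranges, n_glia = as.integer(n_glia),
    glia_rate_factor = glia_rate_factor,
    n_modules = as.integer(n_modules), module_centers = module_centers,
    rho = rho, lambda = lambda, contact_rate = contact_rate,
    area_meanlog = area_meanlog, area_sdlog = area_sdlog,
    dup_frac = dup_frac, contact_jitter = contact_jitter
  ), class = "generator_params")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# scale top-level range lengths by `factor`, preserving class order and
# proportional SAC nesting (used to grow the box for truncation experiments)
scale_ranges <- function(ranges, factor) {
  top <- ranges[is.na(ranges$parent), , drop = FALSE]
  top <- top[order(top$from), , drop = FALSE]
  nested <- ranges[!is.na(ranges$parent), , drop = FALSE]
  len <- pmax(1L, as.integer(round((top$to - top$from + 1L) * factor)))
  to <- cumsum(len)
  from <- to - len + 1L
  out <- data.frame(class = top$class, from = from, to = to,
                    parent = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(nested))) {
    pk <- match(nested$parent[k], top$class)
    off <- nested$from[k] - top$from[pk]
    n_len <- nested$to[k] - nested$from[k] + 1L
    new_off <- as.integer(round(off * factor))
    new_len <- max(1L, as.integer(round(n_len * factor)))
    nf <- min(from[pk] + new_off, to[pk])
    nt <- min(nf + new_len - 1L, to[pk])
    out <- rbind(out, data.frame(class = nested$class[k], from = nf, to = nt,
                                 parent = nested$parent[k],
                                 stringsAsFactors = FALSE))
  }
  out
}

draw_module_centers <- function(M, Lx, Ly) {
  min_sep <- 0.55 * sqrt(Lx * Ly / M)
  centers <- matrix(NA_real_, M, 2)
  for (m in seq_len(M)) {
    for (try in seq_len(500)) {
      cand <- c(stats::runif(1, 0, Lx), stats::runif(1, 0, Ly))
      if (m == 1) break
      dmin <- min(sqrt(rowSums(sweep(centers[seq_len(m - 1), , drop = FALSE],
                                     2, cand)^2)))
      if (dmin >= min_sep) break
    }
    centers[m, ] <- cand
  }
  centers
}

#' Generate a retina-like synthetic sample with known ground truth
#'
#' Places typed neurons (and glia) uniformly in the sample box, assigns
#' every neuron to the planted module whose plane center is nearest, draws
#' per-pair contact counts from the laterally decaying Poisson model, gives
#' each contact a lognormal area and a centroid near the soma midpoint,
#' lists each contact once in random orientation and -- with probability
#' `dup_frac` -- a second time reversed (same area and coordinates), and
#' moves contacts whose centroid falls outside the box to a truncated-link
#' list. The emitted table is row-shuffled.
#'
#' @param params a [generator_params()].
#' @param seed integer seed; output is reproducible bit-for-bit from
#'   `(params, seed)`.
#' @param origin lateral coordinate origin (um), used by the truncation
#'   experiment to embed a core box; default `c(0, 0)`.
#' @return a `synthetic_sample` list: `contacts` (a `contact_table`),
#'   `catalog` (neurons only, with soma coordinates and cBC subtypes),
#'   `truth` (the planted [node_partition()]), `truncated` (contacts lost
#'   to excision), `pair_ledger` (per unordered pair: emitted contact count
#'   and total area, before duplication), `module_centers`, `params`,
#'   `seed`.
#' @export
generate_sample <- function(params = generator_params(), seed = 1L,
                            origin = c(0, 0)) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(seed, {
    box <- params$box
    catalog <- load_cell_catalog(params$ranges)
    n_neuron <- nrow(catalog)
    n_glia <- params$n_glia
    n_all <- n_neuron + n_glia
    ids_all <- c(catalog$id, if (n_glia > 0) max(catalog$id) + seq_len(n_glia))
    is_glia <- c(rep(FALSE, n_neuron), rep(TRUE, n_glia))

    px <- stats::runif(n_all, 0, box[1]) + origin[1]
    py <- stats::runif(n_all, 0, box[2]) + origin[2]
    pz <- stats::runif(n_all, 0, box[3])
    catalog$x <- px[seq_len(n_neuron)]
    catalog$y <- py[seq_len(n_neuron)]
    catalog$z <- pz[seq_len(n_neuron)]

    # cBC subtype labels (uniform over the Off/On config), a few amacrine
    # subtypes for circuit-report realism
    cbc <- which(catalog$cell_class == "cBC")
    catalog$subtype[cbc] <- sample(names(default_off_on_map()),
                                   length(cbc), replace = TRUE)
    nfac <- which(catalog$cell_class == "NFac")
    catalog$subtype[nfac] <- sample(c("A2", "A17", NA, NA, NA, NA),
                                    length(nfac), replace = TRUE)

    centers <- params$module_centers
    if (is.null(centers)) {
      centers <- draw_module_centers(params$n_modules, box[1], box[2])
      centers <- sweep(centers, 2, origin, "+")
    }
    d2c <- outer(px[seq_len(n_neuron)], centers[, 1], "-")^2 +
      outer(py[seq_len(n_neuron)], centers[, 2], "-")^2
    truth_mod <- max.col(-d2c)
    truth <- node_partition(
      stats::setNames(truth_mod, catalog$id), method = "planted", seed = seed
    )

    # pairwise Poisson contact counts
    ut <- which(upper.tri(matrix(0, n_all, n_all)), arr.ind = TRUE)
    ii <- ut[, 1]; jj <- ut[, 2]
    d_lat <- sqrt((px[ii] - px[jj])^2 + (py[ii] - py[jj])^2)
    rate <- params$contact_rate * exp(-d_lat / params$lambda)
    same <- ii <= n_neuron & jj <= n_neuron & truth_mod[pmin(ii, n_neuron)] ==
      truth_mod[pmin(jj, n_neuron)]
    same[ii > n_neuron | jj > n_neuron] <- FALSE
    rate[same] <- rate[same] * params$rho
    gpair <- is_glia[ii] | is_glia[jj]
    rate[gpair] <- rate[gpair] * params$glia_rate_factor
    cnt <- stats::rpois(length(rate), rate)
    keep <- cnt > 0
    pi_ <- ids_all[ii[keep]]; pj_ <- ids_all[jj[keep]]; nk <- cnt[keep]

    ci <- rep(pi_, nk); cj <- rep(pj_, nk)
    n_contacts <- length(ci)
    area <- stats::rlnorm(n_contacts, params$area_meanlog, params$area_sdlog)
    mx <- (px[match(ci, ids_all)] + px[match(cj, ids_all)]) / 2 +
      stats::rnorm(n_contacts, 0, params$contact_jitter)
    my <- (py[match(ci, ids_all)] + py[match(cj, ids_all)]) / 2 +
      stats::rnorm(n_contacts, 0, params$contact_jitter)
    mz <- (pz[match(ci, ids_all)] + pz[match(cj, ids_all)]) / 2 +
      stats::rnorm(n_contacts, 0, params$contact_jitter)

    inside <- mx >= origin[1] & mx <= origin[1] + box[1] &
      my >= origin[2] & my <= origin[2] + box[2] &
      mz >= 0 & mz <= box[3]
    truncated <- data.frame(cell_i = ci[!inside], cell_j = cj[!inside],
                            area = area[!inside], x = mx[!inside],
                            y = my[!inside], z = mz[!inside])
    ci <- ci[inside]; cj <- cj[inside]
    area <- area[inside]; mx <- mx[inside]; my <- my[inside]; mz <- mz[inside]

    # internal ledger of surviving per-pair totals (before duplication)
    key <- paste(pmin(ci, cj), pmax(ci, cj), sep = "_")
    tot <- tapply(area, key, sum)
    nct <- tapply(area, key, length)
    kp <- strsplit(names(tot), "_", fixed = TRUE)
    pair_ledger <- data.frame(
      i = as.integer(vapply(kp, `[`, "", 1L)),
      j = as.integer(vapply(kp, `[`, "", 2L)),
      n_contacts = as.integer(nct),
      total_area = as.numeric(tot)
    )
    pair_ledger <- pair_ledger[order(pair_ledger$i, pair_ledger$j), ]
    rownames(pair_ledger) <- NULL

    # random listing orientation, then reversed duplicates
    swap <- stats::runif(length(ci)) < 0.5
    a1 <- ifelse(swap, cj, ci); b1 <- ifelse(swap, ci, cj)
    dup <- stats::runif(length(ci)) < params$dup_frac
    contacts <- data.frame(
      cell_i = c(a1, b1[dup]), cell_j = c(b1, a1[dup]),
      area = c(area, area[dup]),
      x = c(mx, mx[dup]), y = c(my, my[dup]), z = c(mz, mz[dup])
    )
    contacts <- contacts[sample.int(nrow(contacts)), , drop = FALSE]
    contacts <- new_contact_table(
      contacts,
      c(source = sprintf("synthetic(seed=%d)", seed),
        rows = as.character(nrow(contacts)),
        duplicated_listings = as.character(sum(dup)),
        truncated_contacts = as.character(nrow(truncated)))
    )

    glia <- data.frame(
      id = ids_all[is_glia],
      x = px[is_glia], y = py[is_glia], z = pz[is_glia]
    )
    structure(list(
      contacts = contacts, catalog = catalog, glia = glia, truth = truth,
      truncated = truncated, pair_ledger = pair_ledger,
      module_centers = centers, params = params, seed = seed
    ), class = "synthetic_sample")
  })
}

#' Paired full / excised samples for edge-artifact experiments
#'
#' Draws one sample in a box whose lateral extent is grown by `margin` on
#' all four sides (class counts scaled with the area so density is
#' unchanged), then excises the core box: the truncated twin keeps only
#' neurons inside the core box and the contacts between them, so neurons
#' near the core boundary lose exactly the links that reached outside --
#' the mechanism behind edge-zone degree deficits in excised connectome
#' samples.
#'
#' @param params a [generator_params()].
#' @param margin halo width (um) removed by the excision; `margin = 0`
#'   returns two identical samples.
#' @param seed integer seed.
#' @return list with `full` (the extended-box `synthetic_sample`),
#'   `truncated` (core-box catalog/contacts/truth), and `lost` (contacts
#'   removed by the excision).
#' @export
truncation_experiment <- function(params = generator_params(), margin = 10,
                                  seed = 1L) {
  stopifnot(inherits(params, "generator_params"))
  if (margin < 0 || margin >= min(params$box[1:2]) / 2) {
    stop("`margin` must be in [0, half the smallest lateral extent)")
  }
  box <- params$box
  f_area <- (box[1] + 2 * margin) * (box[2] + 2 * margin) / (box[1] * box[2])
  ext <- params
  ext$box <- c(box[1] + 2 * margin, box[2] + 2 * margin, box[3])
  ext$ranges <- scale_ranges(params$ranges, f_area)
  ext <- do.call(generator_params, ext[setdiff(names(ext), character(0))])
  full <- generate_sample(ext, seed = seed, origin = c(-margin, -margin))

  cat_full <- full$catalog
  # excision is positional: glia inside the core box survive it too (they
  # are removed later, at the catalog-restriction stage of ingest)
  pos <- rbind(cat_full[, c("id", "x", "y")], full$glia[, c("id", "x", "y")])
  in_core_pos <- pos$x >= 0 & pos$x <= box[1] & pos$y >= 0 & pos$y <= box[2]
  core_ids <- pos$id[in_core_pos]
  in_core <- cat_full$id %in% core_ids
  ct <- as.data.frame(full$contacts)
  keep <- ct$cell_i %in% core_ids & ct$cell_j %in% core_ids
  core_cat <- cat_full[in_core, , drop = FALSE]
  class(core_cat) <- class(full$catalog)
  truncated <- list(
    contacts = new_contact_table(
      ct[keep, , drop = FALSE],
      c(attr(full$contacts, "provenance"),
        excised_contacts = as.character(sum(!keep)))
    ),
    catalog = core_cat,
    truth = node_partition(full$truth$membership[as.character(core_cat$id)],
                           method = "planted", seed = seed),
    box = box
  )
  list(full = full, truncated = truncated,
       lost = ct[!keep, , drop = FALSE])
}

#' Edge-vs-core degree deficit of an excised sample
#'
#' Ingests a truncated sample (catalog restriction, per-contact filtering,
#' aggregation), computes weighted degrees, classifies core/edge zones in
#' the core plane and reports the edge deficit.
#'
#' @param truncated the `truncated` element of [truncation_experiment()].
#' @param margin edge-zone margin (um).
#' @param threshold aggregation area threshold (um^2).
#' @return list as [edge_effect_report()], plus the graph.
#' @export
edge_core_deficit <- function(truncated, margin = 10, threshold = 0.16) {
  tbl <- restrict_to_catalog(truncated$contacts, truncated$catalog)
  g <- aggregate_links(tbl, threshold = threshold,
                       filter_mode = "per_contact",
                       node_ids = truncated$catalog$id)
  met <- weighted_degree(g)
  labs <- classify_edge_core(truncated$catalog, margin = margin,
                             plane_bounds = truncated$box[1:2])
  rep <- edge_effect_report(met, labs)
  rep$graph <- g
  rep
}

#' Write a synthetic sample to plain-text files
#'
#' Writes `contacts.csv`, `cells.csv` and `truth_membership.txt` (one
#' `node_id module_id` pair per line) under `dir`.
#'
#' @param sample a `synthetic_sample`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_contact_list(sample$contacts, file.path(dir, "contacts.csv"))
  utils::write.csv(as.data.frame(sample$catalog),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  write_membership(sample$truth, file.path(dir, "truth_membership.txt"))
  invisible(dir)
}
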