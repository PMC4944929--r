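#' Read a raw cell-to-cell contact list
#'
#' Parses a CSV of per-contact records: a cell pair, the apposed membrane
#' contact area (um^2) and the contact centroid coordinates (um). Self
#' contacts (`cell_i == cell_j`) are dropped and counted; rows with
#' non-numeric fields are dropped and reported with their line numbers.
#'
#' @param path CSV file with a header row.
#' @param columns named character vector mapping the canonical names
#'   `cell_i`, `cell_j`, `area`, `x`, `y`, `z` to the column names used in
#'   the file.
#' @return A `contact_table`: a data.frame with columns `cell_i`, `cell_j`,
#'   `area`, `x`, `y`, `z` and a `provenance` attribute (character vector of
#'   applied steps, starting with the source path).
#' @export
read_contact_list <- function(path,
                              columns = c(cell_i = "cell_i", cell_j = "cell_j",
                                          area = "area", x = "x", y = "y", z = "z")) {
  if (!file.exists(path)) stop("contact list not found: ", path)
  canonical <- c("cell_i", "cell_j", "area", "x", "y", "z")
  if (!all(canonical %in% names(columns))) {
    stop("`columns` must map all of: ", paste(canonical, collapse = ", "))
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(unname(columns[canonical]), names(raw))
  if (length(missing) > 0) {
    stop("contact list is missing column(s): ", paste(missing, collapse = ", "))
  }
  dat <- raw[, unname(columns[canonical]), drop = FALSE]
  names(dat) <- canonical
  n_source <- nrow(dat)
  prov <- c(source = path, rows = as.character(n_source))

  bad <- rep(FALSE, n_source)
  for (col in canonical) {
    v <- suppressWarnings(as.numeric(dat[[col]]))
    bad <- bad | is.na(v)
    dat[[col]] <- v
  }
  if (any(bad)) {
    lines <- which(bad) + 1L   # header is line 1
    warning(sprintf("dropped %d malformed row(s) at line(s): %s",
                    sum(bad), paste(utils::head(lines, 20), collapse = ", ")))
    dat <- dat[!bad, , drop = FALSE]
    prov <- c(prov, malformed_dropped = as.character(sum(bad)))
  }
  if (nrow(dat) > 0 && any(dat$area < 0)) {
    stop("negative contact areas found (", sum(dat$area < 0), " rows)")
  }
  dat$cell_i <- as.integer(dat$cell_i)
  dat$cell_j <- as.integer(dat$cell_j)

  self <- dat$cell_i == dat$cell_j
  if (any(self)) dat <- dat[!self, , drop = FALSE]
  prov <- c(prov, self_contacts_dropped = as.character(sum(self)))
  new_contact_table(dat, prov)
}

new_contact_table <- function(df, provenance = character()) {
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("contact_table", "data.frame"))
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("<contact_table> %d contacts\n", nrow(x)))
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("provenance:\n")
    for (i in seq_along(prov)) {
      cat(sprintf("  %s: %s\n", names(prov)[i], prov[i]))
    }
  }
  invisible(x)
}

#' Write a contact table back to CSV
#'
#' Values are written with full double precision so that a write/read
#' round trip reproduces the records exactly.
#'
#' @param table a `contact_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_list <- function(table, path) {
  df <- as.data.frame(table)
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.integer(v)) as.character(v) else sprintf("%.17g", v)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Filter contacts by area threshold
#'
#' Retains contacts whose area meets the synapse-probability threshold.
#' The comparison is inclusive by default (`area >= area_threshold`):
#' the threshold is calibrated as a 50% synapse probability, so boundary
#' contacts are kept.
#'
#' @param table a `contact_table`.
#' @param area_threshold positive area threshold in um^2.
#' @param strict if `TRUE`, use a strict `>` comparison.
#' @return the filtered `contact_table`, with provenance updated.
#' @export
filter_contacts <- function(table, area_threshold, strict = FALSE) {
  if (!is.numeric(area_threshold) || length(area_threshold) != 1 ||
      is.na(area_threshold) || area_threshold <= 0) {
    stop("`area_threshold` must be a single positive number")
  }
  keep <- if (strict) table$area > area_threshold else table$area >= area_threshold
  out <- table[keep, , drop = FALSE]
  prov <- c(attr(table, "provenance"),
            stats::setNames(sprintf("threshold %g um^2 (%s), retained %d of %d",
                                    area_threshold, if (strict) ">" else ">=",
                                    nrow(out), nrow(table)),
                            "area_filter"))
  new_contact_table(as.data.frame(out), prov)
}

#' Aggregate contacts into a weighted graph
#'
#' Pools `(i, j)` and `(j, i)` records by unordered pair, removes exact
#' duplicate listings (identical pair, area and coordinates in either
#' orientation -- the over-counting artifact of contact lists that record
#' some contacts in both orders), sums the surviving contact areas per pair,
#' and expresses each link weight as a multiple of the area threshold.
#'
#' Two filtering conventions are supported. Under `per_contact` (default),
#' individual contacts below `threshold` are removed before summation, so
#' every retained link has weight >= 1 by construction. Under
#' `per_pair_total`, contacts >= `base_threshold` are summed per pair and the
#' pair is kept only if the summed area reaches `threshold`.
#'
#' @param table a `contact_table` (typically already restricted to the
#'   neuron catalog; see [restrict_to_catalog()]).
#' @param threshold area (um^2) that defines unit link weight.
#' @param filter_mode `"per_contact"` or `"per_pair_total"`.
#' @param base_threshold per-contact synapse-probability floor used by
#'   `per_pair_total` mode (um^2).
#' @param node_ids optional integer vector fixing the node set (e.g. all 950
#'   catalog IDs, so that zero-degree neurons stay in the matrix). Contact
#'   IDs absent from `node_ids` raise an error naming the ID.
#' @param dedup_reversed remove exact duplicate listings before summing
#'   (default `TRUE`).
#' @return a [weighted_graph()] with `threshold_used = threshold`.
#' @export
aggregate_links <- function(table, threshold,
                            filter_mode = c("per_contact", "per_pair_total"),
                            base_threshold = 0.08,
                            node_ids = NULL,
                            dedup_reversed = TRUE) {
  filter_mode <- match.arg(filter_mode)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be positive")
  }
  df <- as.data.frame(table)
  if (nrow(df) == 0) stop("no contacts to aggregate")

  if (is.null(node_ids)) {
    node_ids <- sort(unique(c(df$cell_i, df$cell_j)))
  } else {
    node_ids <- as.integer(node_ids)
    unknown <- setdiff(unique(c(df$cell_i, df$cell_j)), node_ids)
    if (length(unknown) > 0) {
      stop("contact references neuron id(s) absent from the node list: ",
           paste(utils::head(sort(unknown), 10), collapse = ", "))
    }
  }

  lo <- pmin(df$cell_i, df$cell_j)
  hi <- pmax(df$cell_i, df$cell_j)
  n_dup <- 0L
  if (dedup_reversed) {
    key <- paste(lo, hi, sprintf("%.12g", df$area),
                 sprintf("%.9g", df$x), sprintf("%.9g", df$y),
                 sprintf("%.9g", df$z), sep = "|")
    dup <- duplicated(key)
    n_dup <- sum(dup)
    if (n_dup > 0) {
      df <- df[!dup, , drop = FALSE]
      lo <- lo[!dup]; hi <- hi[!dup]
    }
  }

  if (filter_mode == "per_contact") {
    keep <- df$area >= threshold
  } else {
    keep <- df$area >= base_threshold
  }
  df <- df[keep, , drop = FALSE]
  lo <- lo[keep]; hi <- hi[keep]
  if (nrow(df) == 0) stop("no contacts survive the area filter")

  pair_key <- paste(lo, hi, sep = "_")
  total <- tapply(df$area, pair_key, sum)
  pk <- strsplit(names(total), "_", fixed = TRUE)
  pi_ <- as.integer(vapply(pk, `[`, "", 1L))
  pj_ <- as.integer(vapply(pk, `[`, "", 2L))
  total <- as.numeric(total)

  if (filter_mode == "per_pair_total") {
    keep_pair <- total >= threshold
    pi_ <- pi_[keep_pair]; pj_ <- pj_[keep_pair]; total <- total[keep_pair]
  }

  n <- length(node_ids)
  A <- matrix(0, n, n)
  ii <- match(pi_, node_ids)
  jj <- match(pj_, node_ids)
  w <- total / threshold
  A[cbind(ii, jj)] <- w
  A[cbind(jj, ii)] <- w
  g <- weighted_graph(A, ids = node_ids, threshold = threshold)
  attr(g, "aggregation") <- list(
    filter_mode = filter_mode,
    duplicates_removed = n_dup,
    contacts_summed = nrow(df),
    links = length(total)
  )
  g
}

#' Drop contacts whose cells are not in the catalog
#'
#' Raw EM contact lists include glia; this removes any record touching an ID
#' outside the neuron catalog and logs the count in the provenance.
#'
#' @param table a `contact_table`.
#' @param catalog a [cell_catalog][load_cell_catalog()].
#' @return the restricted `contact_table`.
#' @export
restrict_to_catalog <- function(table, catalog) {
  ok <- table$cell_i %in% catalog$id & table$cell_j %in% catalog$id
  out <- table[ok, , drop = FALSE]
  prov <- c(attr(table, "provenance"),
            stats::setNames(as.character(sum(!ok)), "non_catalog_contacts_dropped"))
  new_contact_table(as.data.frame(out), prov)
}

#' Read a dense weighted adjacency CSV
#'
#' Accepts the supplementary-matrix dialect: `N` rows by `N` numeric
#' columns, with an optional header row of node IDs (auto-detected).
#' Symmetry is verified to within `tol`.
#'
#' @param path CSV path.
#' @param threshold area threshold the weights are expressed in (um^2),
#'   recorded on the returned graph.
#' @param tol symmetry tolerance.
#' @return a [weighted_graph()].
#' @export
read_adjacency <- function(path, threshold = NA_real_, tol = 1e-9) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n_col <- length(strsplit(lines[1], ",", fixed = TRUE)[[1]])
  # node-ID header rows are numeric too: detect by row/column count
  has_header <- length(lines) == n_col + 1 ||
    anyNA(suppressWarnings(as.numeric(strsplit(lines[1], ",", fixed = TRUE)[[1]])))
  M <- as.matrix(utils::read.csv(text = lines, header = has_header,
                                 check.names = FALSE))
  if (nrow(M) != ncol(M)) {
    stop("adjacency must be square, got ", nrow(M), " x ", ncol(M))
  }
  ids <- if (has_header) as.integer(colnames(M)) else seq_len(ncol(M))
  storage.mode(M) <- "double"
  weighted_graph(M, ids = ids, threshold = threshold, tol = tol)
}

#' Write a weighted adjacency CSV
#'
#' Writes full-precision values with a header row of node IDs so that a
#' write/read round trip is bitwise exact.
#'
#' @param graph a [weighted_graph()].
#' @param path output CSV path.
#' @param header write the node-ID header row (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path, header = TRUE) {
  A <- graph$A
  body <- apply(A, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  lines <- if (header) c(paste(graph$ids, collapse = ","), body) else body
  writeLines(lines, path)
  invisible(path)
}

#' Reproduction counts from a raw EM contact list
#'
#' Runs the ingest battery on the full raw contact list (an external file
#' that ships with the source EM study, not with this package): retention
#' at the 0.08 um^2 synapse-probability threshold, unique ordered pairs
#' among retained contacts, and unique bidirectional links after pooling
#' reversed listings.
#'
#' The file location is taken from `path`, the option
#' `retinaflow.raw_contacts`, or the environment variable
#' `RETINAFLOW_RAW_CONTACTS`. When no file is supplied the function returns
#' `list(status = "unavailable")` rather than failing, so callers can
#' condition on availability.
#'
#' @param path optional explicit CSV path.
#' @param columns column mapping passed to [read_contact_list()].
#' @return list with `status` ("ok"/"unavailable") and, when ok: `n_rows`,
#'   `n_retained`, `retained_fraction`, `n_ordered_pairs`,
#'   `n_bidirectional_links`.
#' @export
raw_contact_reproduction <- function(path = NULL,
                                     columns = c(cell_i = "cell_i",
                                                 cell_j = "cell_j",
                                                 area = "area",
                                                 x = "x", y = "y", z = "z")) {
  if (is.null(path) || !nzchar(path)) {
    path <- getOption("retinaflow.raw_contacts",
                      Sys.getenv("RETINAFLOW_RAW_CONTACTS", ""))
  }
  if (!nzchar(path) || !file.exists(path)) {
    return(list(status = "unavailable"))
  }
  tab <- read_contact_list(path, columns = columns)
  n_rows <- nrow(tab)
  kept <- filter_contacts(tab, 0.08)
  ordered_key <- paste(kept$cell_i, kept$cell_j)
  unordered_key <- paste(pmin(kept$cell_i, kept$cell_j),
                         pmax(kept$cell_i, kept$cell_j))
  list(
    status = "ok",
    n_rows = n_rows,
    n_retained = nrow(kept),
    retained_fraction = nrow(kept) / n_rows,
    n_ordered_pairs = length(unique(ordered_key)),
    n_bidirectional_links = length(unique(unordered_key))
  )
}
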