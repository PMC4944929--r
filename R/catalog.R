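#' Default cell-class ID ranges for the 950-neuron retina sample
#'
#' The sample numbers its neurons sequentially by type: 1-36 ganglion cells
#' (GC), 37-226 near-field amacrine cells (NFac), 227-389 wide-field
#' amacrine cells (WFac) -- among which 260-274 are Off-type and 358-370
#' On-type starburst amacrine cells -- 390-696 cone bipolar cells (cBC),
#' 697-840 rod bipolar cells (rBC) and 841-950 one-of-a-kind "other" cells
#' (putative horizontal cells). The two SAC ranges nest inside WFac.
#'
#' @return data.frame with columns `class`, `from`, `to`, `parent` (NA for
#'   top-level ranges).
#' @export
default_cell_ranges <- function() {
  data.frame(
    class  = c("GC", "NFac", "WFac", "OffSAC", "OnSAC", "cBC", "rBC", "other"),
    from   = c(1L, 37L, 227L, 260L, 358L, 390L, 697L, 841L),
    to     = c(36L, 226L, 389L, 274L, 370L, 696L, 840L, 950L),
    parent = c(NA, NA, NA, "WFac", "WFac", NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Read cell-class ranges from a YAML config
#'
#' Expected layout: a `ranges` list of entries with `class`, `from`, `to`
#' and optional `parent` for nested ranges.
#'
#' @param path YAML file path.
#' @return a ranges data.frame as in [default_cell_ranges()].
#' @export
read_cell_ranges <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$ranges)) stop("YAML config must contain a `ranges` list")
  do.call(rbind, lapply(cfg$ranges, function(r) {
    data.frame(class = r$class, from = as.integer(r$from), to = as.integer(r$to),
               parent = if (is.null(r$parent)) NA_character_ else r$parent,
               stringsAsFactors = FALSE)
  }))
}

#' Build a cell catalog from class ID ranges
#'
#' Every neuron ID gets a class label; IDs in a nested range (the starburst
#' amacrine subranges) carry both the parent class (`cell_class`) and the
#' nested label (`subclass`). Soma coordinates and free-text subtype labels
#' are attached when a soma table is supplied.
#'
#' @param ranges a ranges data.frame ([default_cell_ranges()] layout). The
#'   top-level ranges must tile `1..max(to)` with no gap or overlap; nested
#'   ranges must lie inside their parent.
#' @param soma optional data.frame (or CSV path) with columns `id`, `x`,
#'   `y`, `z` and optionally `subtype`.
#' @return a `cell_catalog`: data.frame with columns `id`, `cell_class`,
#'   `subclass`, `subtype`, `x`, `y`, `z`.
#' @export
load_cell_catalog <- function(ranges = default_cell_ranges(), soma = NULL) {
  top <- ranges[is.na(ranges$parent), , drop = FALSE]
  nested <- ranges[!is.na(ranges$parent), , drop = FALSE]
  top <- top[order(top$from), , drop = FALSE]
  n_max <- max(top$to)

  covered <- integer(0)
  for (k in seq_len(nrow(top))) covered <- c(covered, top$from[k]:top$to[k])
  dup <- unique(covered[duplicated(covered)])
  if (length(dup) > 0) {
    stop("overlapping class ranges at id(s): ",
         paste(utils::head(dup, 10), collapse = ", "))
  }
  gap <- setdiff(seq_len(n_max), covered)
  if (length(gap) > 0) {
    stop("class ranges leave gap(s) at id(s): ",
         paste(utils::head(gap, 10), collapse = ", "))
  }

  id <- seq_len(n_max)
  cell_class <- character(n_max)
  for (k in seq_len(nrow(top))) {
    cell_class[top$from[k]:top$to[k]] <- top$class[k]
  }
  subclass <- rep(NA_character_, n_max)
  for (k in seq_len(nrow(nested))) {
    rng <- nested$from[k]:nested$to[k]
    parent_class <- cell_class[rng]
    if (!all(parent_class == nested$parent[k])) {
      stop("nested range ", nested$class[k], " is not inside its parent ",
           nested$parent[k])
    }
    subclass[rng] <- nested$class[k]
  }

  cat_df <- data.frame(
    id = id, cell_class = cell_class, subclass = subclass,
    subtype = NA_character_, x = NA_real_, y = NA_real_, z = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(soma)) {
    if (is.character(soma)) soma <- utils::read.csv(soma, stringsAsFactors = FALSE)
    m <- match(cat_df$id, soma$id)
    for (col in c("x", "y", "z")) {
      if (!is.null(soma[[col]])) cat_df[[col]] <- soma[[col]][m]
    }
    if (!is.null(soma$subtype)) cat_df$subtype <- as.character(soma$subtype)[m]
  }
  structure(cat_df, class = c("cell_catalog", "data.frame"))
}

#' Look up cell classes for IDs
#'
#' @param catalog a `cell_catalog`.
#' @param ids neuron IDs.
#' @param prefer_subclass return the nested label (e.g. `OffSAC`) where one
#'   exists, instead of the broad class (`WFac`).
#' @return character vector of class labels (`NA` for unknown IDs).
#' @export
cell_class_of <- function(catalog, ids, prefer_subclass = TRUE) {
  m <- match(ids, catalog$id)
  cls <- catalog$cell_class[m]
  if (prefer_subclass) {
    sub <- catalog$subclass[m]
    cls[!is.na(sub)] <- sub[!is.na(sub)]
  }
  cls
}
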