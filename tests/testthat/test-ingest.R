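test_that("read_contact_list drops self-contacts and handles empty files", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_i,cell_j,area,x,y,z",
    "1,2,0.5,1,2,3",
    "3,3,0.4,4,5,6",
    "2,4,0.1,7,8,9"
  ), tmp)
  tab <- read_contact_list(tmp)
  expect_s3_class(tab, "contact_table")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "provenance")[["self_contacts_dropped"]], "1")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("cell_i,cell_j,area,x,y,z", empty)
  expect_equal(nrow(read_contact_list(empty)), 0)
})

test_that("read_contact_list reports missing columns and malformed rows", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_i,cell_j,x,y,z", "1,2,1,2,3"), tmp)
  expect_error(read_contact_list(tmp), "area")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cell_i,cell_j,area,x,y,z",
    "1,2,0.5,1,2,3",
    "1,3,oops,1,2,3"
  ), tmp2)
  expect_warning(tab <- read_contact_list(tmp2), "line")
  expect_equal(nrow(tab), 1)
})

test_that("contact lists round-trip through write/read exactly", {
  set.seed(41)
  n <- 10000
  df <- data.frame(
    cell_i = sample(1:300, n, replace = TRUE),
    cell_j = sample(301:600, n, replace = TRUE),
    area = rlnorm(n, -2.7, 1),
    x = runif(n, 0, 132), y = runif(n, 0, 114), z = runif(n, 0, 80)
  )
  tab <- fixture_contacts(df[, ])
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_contact_list(tab, tmp)
  back <- read_contact_list(tmp)
  expect_identical(as.data.frame(back)[names(df)], df)
})

test_that("filter_contacts keeps the boundary and matches a direct scan", {
  tab <- fixture_contacts(data.frame(
    cell_i = c(1, 1, 1), cell_j = c(2, 3, 4), area = c(0.07, 0.08, 0.09)
  ))
  expect_equal(nrow(filter_contacts(tab, 0.08)), 2)
  expect_equal(nrow(filter_contacts(tab, 0.08, strict = TRUE)), 1)
  expect_error(filter_contacts(tab, -0.1), "positive")

  set.seed(7)
  n <- 5000
  big <- fixture_contacts(data.frame(
    cell_i = sample(1:50, n, TRUE), cell_j = sample(51:100, n, TRUE),
    area = rlnorm(n, -2.5, 1)
  ))
  thr <- stats::median(big$area)
  expect_equal(nrow(filter_contacts(big, thr)), sum(big$area >= thr))
})

test_that("aggregate_links pools reversed listings and scales by threshold", {
  # distinct coordinates: two physical contacts listed in opposite orders
  tab <- fixture_contacts(data.frame(
    cell_i = c(1, 2), cell_j = c(2, 1), area = c(0.16, 0.16)
  ))
  g <- aggregate_links(tab, threshold = 0.16)
  expect_equal(g$A["1", "2"], 2.0)

  one <- fixture_contacts(data.frame(cell_i = 1, cell_j = 2, area = 0.32))
  expect_equal(aggregate_links(one, 0.16)$A["1", "2"], 2.0)
})

test_that("aggregate_links removes exact duplicate reversed listings", {
  # same area AND coordinates in both orders: the over-counting artifact
  tab <- retinaflow:::new_contact_table(data.frame(
    cell_i = c(1, 2), cell_j = c(2, 1), area = c(0.16, 0.16),
    x = c(5, 5), y = c(6, 6), z = c(7, 7)
  ))
  g <- aggregate_links(tab, threshold = 0.16)
  expect_equal(g$A["1", "2"], 1.0)
  expect_equal(attr(g, "aggregation")$duplicates_removed, 1L)
})

test_that("aggregate_links matches a hash-map summation oracle", {
  set.seed(11)
  n <- 2000
  df <- data.frame(
    cell_i = sample(1:40, n, TRUE), cell_j = sample(1:40, n, TRUE),
    area = rlnorm(n, -2, 0.8)
  )
  df <- df[df$cell_i != df$cell_j, ]
  tab <- fixture_contacts(df)
  thr <- 0.16
  g <- aggregate_links(tab, thr, filter_mode = "per_contact")

  env <- new.env()
  for (r in seq_len(nrow(df))) {
    if (df$area[r] < thr) next
    key <- paste(min(df$cell_i[r], df$cell_j[r]),
                 max(df$cell_i[r], df$cell_j[r]))
    env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + df$area[r]
  }
  for (key in ls(env)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    expect_equal(g$A[as.character(ij[1]), as.character(ij[2])],
                 env[[key]] / thr)
  }
  expect_equal(sum(g$A > 0) / 2, length(ls(env)))
})

test_that("aggregation is invariant to record order and orientation", {
  set.seed(21)
  n <- 800
  df <- data.frame(
    cell_i = sample(1:25, n, TRUE), cell_j = sample(26:50, n, TRUE),
    area = rlnorm(n, -2, 1),
    x = runif(n), y = runif(n), z = runif(n)
  )
  tab <- retinaflow:::new_contact_table(df)
  g0 <- aggregate_links(tab, 0.1)

  perm <- sample(n)
  df2 <- df[perm, ]
  flip <- runif(n) < 0.5
  tmp <- df2$cell_i[flip]
  df2$cell_i[flip] <- df2$cell_j[flip]
  df2$cell_j[flip] <- tmp
  g1 <- aggregate_links(retinaflow:::new_contact_table(df2), 0.1)
  expect_identical(g0$ids, g1$ids)
  expect_equal(g0$A, g1$A)
})

test_that("total weight conserves retained contact area", {
  set.seed(31)
  n <- 1500
  tab <- fixture_contacts(data.frame(
    cell_i = sample(1:30, n, TRUE), cell_j = sample(31:60, n, TRUE),
    area = rlnorm(n, -2.2, 1)
  ))
  thr <- 0.16
  g <- aggregate_links(tab, thr, filter_mode = "per_contact")
  retained <- sum(tab$area[tab$area >= thr])
  expect_equal(sum(g$A) * thr / 2, retained)
})

test_that("per_contact links are a subset of per_pair_total links", {
  set.seed(51)
  n <- 3000
  tab <- fixture_contacts(data.frame(
    cell_i = sample(1:30, n, TRUE), cell_j = sample(31:60, n, TRUE),
    area = rlnorm(n, -2.6, 1)
  ))
  thr <- 0.16
  ids <- 1:60
  g_pc <- aggregate_links(tab, thr, "per_contact", node_ids = ids)
  g_pt <- aggregate_links(tab, thr, "per_pair_total", node_ids = ids)
  expect_true(all(g_pt$A[g_pc$A > 0] > 0))
  # and per-pair totals dominate per-contact totals
  expect_true(all(g_pt$A >= g_pc$A - 1e-12))
})

test_that("aggregate_links errors on IDs missing from a fixed node list", {
  tab <- fixture_contacts(data.frame(cell_i = 1, cell_j = 99, area = 1))
  expect_error(aggregate_links(tab, 0.16, node_ids = 1:10), "99")
})

test_that("adjacency CSVs round-trip bitwise and reject bad input", {
  set.seed(13)
  A <- matrix(rlnorm(2500), 50, 50)
  A <- A + t(A)
  diag(A) <- 0
  A[A < 1] <- 0
  g <- weighted_graph(A, ids = sample(1000:2000, 50))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(g, tmp)
  back <- read_adjacency(tmp, threshold = 0.16)
  expect_identical(unname(back$A), unname(g$A))
  expect_identical(back$ids, g$ids)
  expect_equal(back$threshold, 0.16)

  # 2x2 zero matrix: a graph with no links
  tmp0 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0", "0,0"), tmp0)
  g0 <- read_adjacency(tmp0)
  expect_equal(sum(g0$A), 0)

  tmp1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,2", "1,0,3"), tmp1)
  expect_error(read_adjacency(tmp1), "square")

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1", "2,0"), tmp2)
  expect_error(read_adjacency(tmp2), "symmetric")
})

test_that("cell catalog labels the canonical ID ranges", {
  cat950 <- load_cell_catalog()
  expect_equal(nrow(cat950), 950)
  expect_equal(cell_class_of(cat950, 260), "OffSAC")
  expect_equal(cat950$cell_class[260], "WFac")
  expect_equal(cell_class_of(cat950, 1), "GC")
  expect_equal(cell_class_of(cat950, 364), "OnSAC")
  expect_equal(cell_class_of(cat950, 950), "other")

  custom <- data.frame(class = c("GC", "cBC"), from = c(1L, 4L), to = c(3L, 6L),
                       parent = NA_character_)
  expect_equal(cell_class_of(load_cell_catalog(custom), 5), "cBC")
})

test_that("cell catalog rejects gaps and overlaps", {
  gap <- data.frame(class = c("GC", "cBC"), from = c(1L, 5L), to = c(3L, 6L),
                    parent = NA_character_)
  expect_error(load_cell_catalog(gap), "gap")
  ovl <- data.frame(class = c("GC", "cBC"), from = c(1L, 3L), to = c(3L, 6L),
                    parent = NA_character_)
  expect_error(load_cell_catalog(ovl), "overlap")
})

test_that("restrict_to_catalog drops glia contacts with a logged count", {
  cat6 <- load_cell_catalog(data.frame(class = "GC", from = 1L, to = 6L,
                                       parent = NA_character_))
  tab <- fixture_contacts(data.frame(
    cell_i = c(1, 2, 7), cell_j = c(2, 8, 8), area = c(1, 1, 1)
  ))
  out <- restrict_to_catalog(tab, cat6)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "provenance")[["non_catalog_contacts_dropped"]], "2")
})

test_that("YAML range configs load and match the built-in defaults", {
  path <- system.file("extdata", "cell_ranges.yaml", package = "retinaflow")
  rng <- read_cell_ranges(path)
  cat_yaml <- load_cell_catalog(rng)
  cat_default <- load_cell_catalog()
  expect_equal(cat_yaml$cell_class, cat_default$cell_class)
  expect_equal(cat_yaml$subclass, cat_default$subclass)
})
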