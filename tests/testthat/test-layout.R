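test_that("graph distances are BFS hop counts with Inf for disconnected", {
  D <- graph_distances(fixture_path3())
  expect_equal(D["1", "3"], 2)
  expect_equal(diag(D), setNames(rep(0, 3), 1:3))

  two <- fixture_disjoint_cliques(k = 3)
  D2 <- graph_distances(two)
  expect_true(all(is.infinite(D2[1:3, 4:6])))
})

test_that("hop distances match a boolean matrix-power oracle", {
  set.seed(19)
  g <- rand_graph(50, 0.08)
  D <- graph_distances(g)
  B <- g$A > 0
  reach <- diag(TRUE, 50)
  Dorc <- matrix(Inf, 50, 50)
  diag(Dorc) <- 0
  cur <- reach
  for (step in 1:50) {
    cur <- (cur %*% B) > 0
    newly <- cur & Dorc == Inf & !diag(TRUE, 50)
    Dorc[newly] <- step
    if (!any(newly)) break
  }
  expect_equal(unname(D), Dorc)
})

test_that("classical scaling reproduces line and simplex geometries", {
  D3 <- graph_distances(fixture_path3())
  # a path is exactly line-embeddable: one positive eigenvalue, flagged
  expect_warning(lay <- sde_layout(D3, dims = 2), "positive")
  X <- as.matrix(lay$coords[, c("X1", "X2")])
  pd <- as.matrix(dist(X))
  expect_equal(pd["1", "2"], 1, tolerance = 1e-9)
  expect_equal(pd["2", "3"], 1, tolerance = 1e-9)
  expect_equal(pd["1", "3"], 2, tolerance = 1e-9)
  expect_lt(lay$stress, 1e-8)

  # complete graph on 4 nodes: unit-edge regular tetrahedron in 3D
  K4 <- weighted_graph({A <- matrix(1, 4, 4); diag(A) <- 0; A})
  lay4 <- sde_layout(graph_distances(K4), dims = 3)
  pd4 <- as.matrix(dist(as.matrix(lay4$coords[, c("X1", "X2", "X3")])))
  expect_equal(unname(pd4[upper.tri(pd4)]), rep(1, 6), tolerance = 1e-9)
  expect_lt(lay4$stress, 1e-8)
})

test_that("Euclidean-realizable distances embed with zero stress", {
  set.seed(42)
  P <- matrix(runif(30), 15, 2)
  D <- as.matrix(dist(P))
  lay <- sde_layout(D, dims = 2)
  expect_lt(lay$stress, 1e-8)
})

test_that("layout is deterministic and unique up to rigid motion", {
  set.seed(55)
  g <- rand_graph(20, 0.25)
  D <- graph_distances(g)
  if (any(is.infinite(D))) {
    comp <- igraph::components(as_igraph(g))
    g <- subgraph_of(g, g$ids[comp$membership == which.max(comp$csize)])
    D <- graph_distances(g)
  }
  l1 <- sde_layout(D, dims = 2)
  l2 <- sde_layout(D, dims = 2)
  expect_identical(l1$coords, l2$coords)

  # Procrustes: distances are preserved exactly between runs
  X1 <- as.matrix(l1$coords[, c("X1", "X2")])
  X2 <- as.matrix(l2$coords[, c("X1", "X2")])
  expect_lt(max(abs(dist(X1) - dist(X2))), 1e-8)
})

test_that("embedding stress is near a numerical MDS optimum", {
  set.seed(77)
  g <- rand_graph(20, 0.3)
  comp <- igraph::components(as_igraph(g))
  g <- subgraph_of(g, g$ids[comp$membership == which.max(comp$csize)])
  D <- graph_distances(g)
  lay <- sde_layout(D, dims = 2)
  stress_num <- smacof_mds(D, dims = 2, iters = 1000)
  # classical scaling solves the spectral (strain) problem, not raw stress:
  # on non-Euclidean geodesics it trails an iterative stress minimizer by a
  # bounded factor, and matches it (both ~0) when D is Euclidean-realizable
  expect_lt(lay$stress, 2 * stress_num)

  P <- matrix(runif(24), 12, 2)
  De <- as.matrix(dist(P))
  expect_lt(abs(sde_layout(De, dims = 2)$stress - smacof_mds(De, 2, 1000)),
            0.01 * sum(De^2) / 2 + 1e-6)
})

test_that("disconnected nodes are ring-placed and flagged", {
  two <- fixture_disjoint_cliques(k = 4)
  A <- two$A
  A[1, 5] <- 0  # keep disjoint
  lay <- sde_layout(graph_distances(two), dims = 2)
  expect_equal(sum(lay$coords$in_embedding), 4)
  outs <- lay$coords[!lay$coords$in_embedding, ]
  r_main <- max(sqrt(rowSums(
    as.matrix(lay$coords[lay$coords$in_embedding, c("X1", "X2")])^2)))
  r_out <- sqrt(outs$X1^2 + outs$X2^2)
  expect_true(all(r_out >= r_main))
})

test_that("anatomical layout maps classes to layer depths", {
  cat950 <- load_cell_catalog()
  cat950$x <- runif(950, 0, 132)
  cat950$y <- runif(950, 0, 114)
  lay <- anatomical_layout(cat950)
  expect_equal(unique(lay$depth[cat950$cell_class == "cBC"]), 0.1)
  expect_equal(unique(lay$depth[cat950$cell_class == "GC"]), 0.9)

  custom <- anatomical_layout(cat950, depth_by_class = c(
    GC = 0.5, NFac = 0.2, WFac = 0.2, cBC = 0.1, rBC = 0.1, other = 0.3))
  expect_equal(unique(custom$depth[cat950$cell_class == "GC"]), 0.5)

  expect_error(anatomical_layout(cat950, depth_by_class = c(GC = 0.9)),
               "class")
})

test_that("strong-link subgraph keeps exactly the focus-incident links", {
  set.seed(61)
  g <- rand_graph(30, 0.3, wchoices = c(1, 5, 20))
  focus <- c(3, 7)
  sub <- strong_link_subgraph(g, focus, weight_min = 10)
  ed <- graph_edges(sub)
  expect_true(all(ed$i %in% focus | ed$j %in% focus))
  expect_true(all(ed$weight > 10))
  n_expected <- sum(g$A[focus, ] > 10) - sum(g$A[focus, focus] > 10) / 2 * 0
  # count links incident to focus with weight > 10 (focus-focus once)
  M <- g$A > 10
  n_direct <- sum(M[focus, ]) - sum(M[focus, focus]) / 2
  expect_equal(attr(sub, "n_links"), as.integer(n_direct))

  # weight_min = Inf keeps focus nodes only, no links
  empty <- strong_link_subgraph(g, focus, weight_min = Inf)
  expect_equal(empty$ids, focus)
  expect_equal(attr(empty, "n_links"), 0L)

  expect_error(strong_link_subgraph(g, 999), "999")
})

test_that("raising weight_min never adds links", {
  set.seed(62)
  g <- rand_graph(25, 0.4, wchoices = c(1, 2, 8, 16))
  focus <- 1:4
  prev <- Inf
  for (wm in c(0, 1, 4, 12)) {
    n <- attr(strong_link_subgraph(g, focus, weight_min = wm), "n_links")
    if (is.finite(prev)) expect_lte(n, prev)
    prev <- n
  }
})

test_that("render_view writes a figure file", {
  set.seed(63)
  g <- rand_graph(5, 0.8)
  D <- graph_distances(g)
  lay <- sde_layout(D, dims = 2)
  part <- node_partition(named_membership(1:5, c(1, 1, 2, 2, 2)))
  f <- withr::local_tempfile(fileext = ".png")
  render_view(lay$coords, g, part, file = f)
  expect_true(file.exists(f))
  expect_gt(file.info(f)$size, 1000)
})
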