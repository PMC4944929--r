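test_that("stationary flow is strength-proportional", {
  p4 <- stationary_flow(fixture_cycle4())
  expect_equal(unname(p4), rep(0.25, 4))

  ps <- stationary_flow(fixture_star(leaves = 4, w = 2))
  expect_equal(unname(ps[1]), 0.5)
  expect_equal(unname(ps[-1]), rep(0.125, 4))

  expect_error(stationary_flow(weighted_graph(matrix(0, 2, 2))), "no links")
})

test_that("stationary flow matches empirical visit rates of a long walk", {
  set.seed(88)
  g <- rand_graph(10, 0.5)
  comp <- igraph::components(as_igraph(g))
  keep <- which(comp$membership == which.max(comp$csize))
  g <- subgraph_of(g, g$ids[keep])
  p <- stationary_flow(g)

  # 2000 parallel walkers x 600 steps, first 100 discarded as burn-in
  A <- g$A
  n <- nrow(A)
  n_walk <- 2000
  visits <- numeric(n)
  pos <- sample.int(n, n_walk, replace = TRUE)
  trans <- A / rowSums(A)
  cum <- t(apply(trans, 1, cumsum))
  for (step in 1:600) {
    u <- runif(n_walk)
    # vectorized categorical draw: count thresholds below u per walker
    pos <- rowSums(cum[pos, , drop = FALSE] < u) + 1L
    if (step > 100) visits <- visits + tabulate(pos, n)
  }
  emp <- visits / sum(visits)
  expect_lt(max(abs(emp - unname(p))), 1e-3 + 3 * sqrt(max(p) / sum(visits) * n))
})

test_that("codelength reproduces the closed forms", {
  g4 <- fixture_cycle4()
  expect_equal(map_codelength(g4, node_partition(named_membership(1:4, rep(1, 4)))),
               2.0)
  D <- matrix(0, 4, 4); D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 1
  gd <- weighted_graph(D)
  expect_equal(map_codelength(gd, node_partition(named_membership(1:4, c(1, 1, 2, 2)))),
               1.0)
  expect_equal(map_codelength(gd, node_partition(named_membership(1:4, rep(1, 4)))),
               2.0)
})

test_that("codelength is invariant under module relabeling", {
  set.seed(3)
  g <- rand_graph(15, 0.3)
  memb <- sample(1:4, 15, replace = TRUE)
  L1 <- map_codelength(g, node_partition(named_membership(1:15, memb)))
  relab <- c(3, 1, 4, 2)[memb]
  L2 <- map_codelength(g, node_partition(named_membership(1:15, relab)))
  expect_equal(L1, L2)
})

test_that("codelength agrees with the independent formula oracle", {
  set.seed(14)
  for (rep in 1:20) {
    g <- rand_graph(9, 0.4)
    if (sum(g$A) == 0) next
    memb <- sample(1:3, 9, replace = TRUE)
    expect_equal(map_codelength(g, node_partition(named_membership(1:9, memb))),
                 oracle_codelength(g, memb))
  }
})

test_that("greedy search finds the exhaustive optimum on a planted graph", {
  g <- fixture_two_cliques(k = 4)
  res <- infomap_partition(g, seed = 5, trials = 10)
  expect_equal(res$codelength, oracle_min_codelength(g), tolerance = 1e-9)
  m <- res$partition$membership
  expect_equal(length(unique(m)), 2)
  expect_equal(length(unique(m[1:4])), 1)
  expect_equal(length(unique(m[5:8])), 1)
})

test_that("infomap separates two 5-cliques joined by one link", {
  g <- fixture_two_cliques(k = 5)
  res <- infomap_partition(g, seed = 1, trials = 5)
  m <- unname(res$partition$membership)
  expect_equal(length(unique(m)), 2)
  expect_equal(length(unique(m[1:5])), 1)
  expect_equal(length(unique(m[6:10])), 1)
  expect_false(m[1] == m[6])
})

test_that("infomap is reproducible bit-for-bit and orders modules by flow", {
  set.seed(6)
  g <- rand_graph(40, 0.15)
  r1 <- infomap_partition(g, seed = 42, trials = 8)
  r2 <- infomap_partition(g, seed = 42, trials = 8)
  expect_identical(r1$partition$membership, r2$partition$membership)
  expect_identical(r1$codelength, r2$codelength)
  fl <- r1$flow$modules$p_internal
  # labels sorted by decreasing internal flow
  expect_true(all(diff(fl) <= 1e-12))
})

test_that("zero-degree nodes become trailing singleton modules", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  g <- weighted_graph(A)
  res <- infomap_partition(g, seed = 1, trials = 2)
  m <- res$partition$membership
  expect_true(all(m[c("4", "5")] > max(m[c("1", "2", "3")])))
  expect_equal(length(unique(m[c("4", "5")])), 2)
  p <- res$flow$p
  expect_equal(unname(p[c("4", "5")]), c(0, 0))
})

test_that("modularity Q matches closed forms and the double-sum oracle", {
  set.seed(30)
  g <- rand_graph(20, 0.3)
  expect_equal(modularity_Q(g, node_partition(named_membership(1:20, rep(1, 20)))),
               0)
  gd <- fixture_disjoint_cliques(k = 4)
  split <- node_partition(named_membership(1:8, rep(1:2, each = 4)))
  expect_equal(modularity_Q(gd, split), 0.5)

  memb <- sample(1:4, 20, replace = TRUE)
  expect_equal(modularity_Q(g, node_partition(named_membership(1:20, memb))),
               oracle_modularity(g, memb))
})

test_that("divisive and agglomerative methods split the two-triangle toy", {
  g <- fixture_two_cliques(k = 3)
  truth <- named_membership(1:6, rep(1:2, each = 3))

  gn <- girvan_newman(g, target_modules = 2, use_weights = FALSE)
  expect_equal(partition_similarity(gn, node_partition(truth)), 1)

  # the bridge carries the highest edge betweenness, so it is cut first:
  # after one removal the graph already has 2 components
  bc <- betweenness_centrality(g, use_weights = FALSE)
  top <- bc$edges[which.max(bc$edges$ebc), ]
  expect_equal(c(top$i, top$j), c(3, 4))

  cnm <- cnm_agglomerative(g)
  expect_equal(partition_similarity(cnm, node_partition(truth)), 1)
})

test_that("spectral partition recovers planted cliques and scans Q", {
  g <- fixture_two_cliques(k = 5)
  truth <- node_partition(named_membership(1:10, rep(1:2, each = 5)))
  for (basis in c("laplacian", "modularity_matrix")) {
    sp <- spectral_partition(g, k = 2, basis = basis, seed = 3)
    expect_equal(partition_similarity(sp, truth), 1)
  }
  scan <- spectral_partition(g, k = NULL, k_range = 2:5, seed = 3)
  expect_equal(attr(scan, "quality_scan")$k, 2:5)
  best_k <- attr(scan, "quality_scan")$k[which.max(attr(scan, "quality_scan")$Q)]
  expect_equal(best_k, 2)
})

test_that("participation coefficients follow the definition", {
  # all weight inside own module -> 0
  gd <- fixture_disjoint_cliques(k = 4)
  part <- node_partition(named_membership(1:8, rep(1:2, each = 4)))
  expect_equal(unname(participation_coefficients(gd, part)), rep(0, 8))

  # node 1 split equally across two modules -> 0.5
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[1, 3] <- A[3, 1] <- 1
  g <- weighted_graph(A)
  part2 <- node_partition(named_membership(1:3, c(1, 1, 2)))
  expect_equal(unname(participation_coefficients(g, part2))[1], 0.5)
})

test_that("module flow table sums member visit rates", {
  gd <- fixture_disjoint_cliques(k = 4)
  part <- node_partition(named_membership(1:8, rep(1:2, each = 4)))
  fs <- flow_summary(gd, part)
  tab <- module_flow_table(fs, part)
  expect_equal(tab$flow, c(0.5, 0.5))
  expect_equal(tab$n_members, c(4L, 4L))

  set.seed(44)
  g <- rand_graph(20, 0.3)
  memb <- named_membership(1:20, sample(1:3, 20, TRUE))
  part2 <- node_partition(memb)
  fs2 <- flow_summary(g, part2)
  p <- fs2$p
  for (mm in 1:3) {
    expect_equal(fs2$modules$p_internal[mm],
                 sum(p[names(memb)[memb == mm]]))
  }
})

test_that("adjusted Rand index matches its contingency formula", {
  ids <- 1:4
  p1 <- node_partition(named_membership(ids, rep(1, 4)))
  expect_equal(partition_similarity(p1, p1), 1.0)
  singles <- node_partition(named_membership(ids, 1:4))
  expect_equal(partition_similarity(p1, singles), 0.0)

  set.seed(77)
  for (rep in 1:10) {
    m1 <- sample(1:4, 30, TRUE)
    m2 <- sample(1:3, 30, TRUE)
    got <- partition_similarity(node_partition(named_membership(1:30, m1)),
                                node_partition(named_membership(1:30, m2)))
    expect_equal(got, oracle_ari_pairs(m1, m2))
    if (requireNamespace("mclust", quietly = TRUE)) {
      expect_equal(got, mclust::adjustedRandIndex(m1, m2))
    }
  }
  expect_error(
    partition_similarity(p1, node_partition(named_membership(2:5, 1:4))),
    "node set"
  )
})

test_that("own map-equation search agrees with igraph's InfoMap on planted cliques", {
  set.seed(10)
  # planted 4-clique ring: unambiguous module structure
  k <- 5; blocks <- 4
  n <- k * blocks
  A <- matrix(0, n, n)
  for (b in seq_len(blocks)) {
    idx <- ((b - 1) * k + 1):(b * k)
    A[idx, idx] <- 1
  }
  diag(A) <- 0
  for (b in seq_len(blocks)) {
    a <- b * k
    z <- (b %% blocks) * k + 1
    A[a, z] <- A[z, a] <- 1
  }
  g <- weighted_graph(A)
  mine <- infomap_partition(g, seed = 2, trials = 10)$partition
  gi <- as_igraph(g)
  ref <- igraph::cluster_infomap(gi, e.weights = igraph::E(gi)$weight)
  refp <- node_partition(stats::setNames(igraph::membership(ref),
                                         igraph::V(gi)$name))
  expect_equal(partition_similarity(mine, refp), 1)
})
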