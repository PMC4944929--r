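# Independent brute-force oracles used to pin down expected values.
# These deliberately use different algorithms from the implementation
# (Floyd-Warshall + path enumeration instead of Brandes; direct double
# sums instead of igraph; full set-partition enumeration instead of the
# greedy search).

# random symmetric weighted graph; weights from `wchoices` (powers of two
# keep inverse-length sums exact, so geodesic ties are exact in floating
# point for implementation and oracle alike)
rand_graph <- function(n, p = 0.35, wchoices = c(1, 2, 4)) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        w <- sample(wchoices, 1)
        A[i, j] <- w
        A[j, i] <- w
      }
    }
  }
  weighted_graph(A)
}

# all-pairs shortest path lengths by Floyd-Warshall on a length matrix
floyd_warshall <- function(len) {
  n <- nrow(len)
  D <- len
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

# exhaustive betweenness: enumerate every geodesic path per unordered pair,
# share credit equally; endpoints excluded for nBC
oracle_betweenness <- function(graph, use_weights = TRUE) {
  A <- graph$A
  n <- nrow(A)
  len <- matrix(Inf, n, n)
  len[A > 0] <- if (use_weights) 1 / A[A > 0] else 1
  D <- floyd_warshall(len)
  nbc <- numeric(n)
  ebc <- matrix(0, n, n)
  tol <- 1e-9

  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      paths <- list()
      walk <- function(v, cur, path) {
        if (v == t) {
          paths[[length(paths) + 1]] <<- path
          return()
        }
        for (u in which(is.finite(len[v, ]))) {
          if (u %in% path) next
          if (cur + len[v, u] + D[u, t] <= D[s, t] + tol) {
            walk(u, cur + len[v, u], c(path, u))
          }
        }
      }
      walk(s, 0, s)
      sigma <- length(paths)
      for (pth in paths) {
        if (length(pth) > 2) {
          nbc[pth[-c(1, length(pth))]] <- nbc[pth[-c(1, length(pth))]] + 1 / sigma
        }
        for (e in seq_len(length(pth) - 1)) {
          a <- pth[e]; b <- pth[e + 1]
          ebc[a, b] <- ebc[a, b] + 1 / sigma
          ebc[b, a] <- ebc[b, a] + 1 / sigma
        }
      }
    }
  }
  list(nbc = stats::setNames(nbc, graph$ids),
       ebc = (ebc + t(ebc)) / 2)  # symmetric accumulation done twice above
}

# all set partitions of n elements as membership vectors (restricted growth)
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(memb, used) {
    i <- length(memb) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return()
    }
    for (lab in seq_len(used + 1)) {
      rec(c(memb, lab), max(used, lab))
    }
  }
  rec(integer(0), 0L)
  out
}

# lean independent codelength evaluator (direct formula on a membership
# vector aligned with graph$ids)
oracle_codelength <- function(graph, memb) {
  A <- graph$A
  two_w <- sum(A)
  k <- rowSums(A)
  p <- k / two_w
  plp <- function(x) {
    y <- x[x > 0]
    sum(y * log2(y))
  }
  mods <- unique(memb)
  q_mod <- vapply(mods, function(mm) {
    inm <- memb == mm
    sum(A[inm, !inm]) / two_w
  }, 0)
  p_mod <- vapply(mods, function(mm) sum(p[memb == mm]), 0)
  q <- sum(q_mod)
  plp(q) - 2 * plp(q_mod) + plp(p_mod + q_mod) - plp(p)
}

# exhaustive map-equation minimum over all set partitions (small n only)
oracle_min_codelength <- function(graph, partitions = NULL) {
  n <- length(graph$ids)
  if (is.null(partitions)) partitions <- enumerate_partitions(n)
  best <- Inf
  for (memb in partitions) {
    L <- oracle_codelength(graph, memb)
    if (L < best) best <- L
  }
  best
}

# direct O(N^2) modularity double sum
oracle_modularity <- function(graph, memb) {
  A <- graph$A
  two_w <- sum(A)
  k <- rowSums(A)
  s <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) s <- s + A[i, j] - k[i] * k[j] / two_w
    }
  }
  unname(s / two_w)
}

# ARI from first principles on a pair-counting basis (quadratic, tiny n)
oracle_ari_pairs <- function(m1, m2) {
  n <- length(m1)
  same1 <- outer(m1, m1, "==")[upper.tri(diag(n))]
  same2 <- outer(m2, m2, "==")[upper.tri(diag(n))]
  a <- sum(same1 & same2)
  total <- length(same1)
  e1 <- sum(same1); e2 <- sum(same2)
  b <- sum(!same1 & !same2)
  expected <- (e1 * e2 + (total - e1) * (total - e2)) / total
  ((a + b) - expected) / (total - expected)
}

# simple SMACOF majorization MDS: an independent numerical check on the
# spectral embedding's stress
smacof_mds <- function(D, dims = 2, iters = 300) {
  n <- nrow(D)
  set.seed(99)
  X <- matrix(stats::rnorm(n * dims), n, dims) * mean(D) / 2
  for (it in seq_len(iters)) {
    E <- as.matrix(stats::dist(X))
    B <- matrix(0, n, n)
    pos <- E > 1e-12
    B[pos] <- -D[pos] / E[pos]
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  sum((as.matrix(stats::dist(X)) - D)^2) / 2
}
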