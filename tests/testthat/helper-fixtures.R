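# small deterministic fixtures built in code

# path a-b-c with unit weights (ids 1,2,3)
fixture_path3 <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  weighted_graph(A)
}

fixture_cycle4 <- function() {
  A <- matrix(0, 4, 4)
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1
  weighted_graph(A + t(A))
}

# two k-cliques joined by a single unit bridge (clique1: 1..k, clique2: k+1..2k)
fixture_two_cliques <- function(k = 3) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[1:k, 1:k] <- 1
  A[(k + 1):n, (k + 1):n] <- 1
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- 1
  weighted_graph(A)
}

# two disjoint equal cliques, no bridge
fixture_disjoint_cliques <- function(k = 4) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[1:k, 1:k] <- 1
  A[(k + 1):n, (k + 1):n] <- 1
  diag(A) <- 0
  weighted_graph(A)
}

fixture_star <- function(leaves = 4, w = 2) {
  n <- leaves + 1
  A <- matrix(0, n, n)
  A[1, 2:n] <- w
  A[2:n, 1] <- w
  weighted_graph(A)
}

# contact-table fixture with explicit coordinates
fixture_contacts <- function(df) {
  df$x <- if (is.null(df$x)) seq_len(nrow(df)) else df$x
  df$y <- if (is.null(df$y)) seq_len(nrow(df)) else df$y
  df$z <- if (is.null(df$z)) seq_len(nrow(df)) else df$z
  retinaflow:::new_contact_table(df)
}

# a small fast generator configuration for pipeline tests
small_params <- function(...) {
  ranges <- data.frame(
    class = c("GC", "NFac", "WFac", "cBC", "rBC", "other"),
    from = c(1L, 9L, 49L, 89L, 165L, 201L),
    to = c(8L, 48L, 88L, 164L, 200L, 220L),
    parent = NA_character_, stringsAsFactors = FALSE
  )
  generator_params(box = c(66, 57, 40), ranges = ranges, n_glia = 20,
                   n_modules = 4, ...)
}

# membership vector named by ids
named_membership <- function(ids, labels) stats::setNames(labels, ids)
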