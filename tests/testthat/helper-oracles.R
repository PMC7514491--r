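# Brute-force reference implementations, kept deliberately independent of the
# package's code paths: balls come from shortest-path distances, matrices from
# double loops over explicit set operations, metrics from direct evaluation of
# their defining sums.

oracle_density <- function(g, v, h) {
  d <- igraph::distances(g, v = v)
  ball <- which(d[1, ] <= h)
  if (length(ball) <= 1L) return(0)
  sub <- igraph::induced_subgraph(g, ball)
  igraph::ecount(sub) / choose(length(ball), 2)
}

oracle_jaccard_matrix <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  J <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      u <- union(adj[[i]], adj[[j]])
      J[i, j] <- if (length(u) == 0L) 0 else
        length(intersect(adj[[i]], adj[[j]])) / length(u)
    }
  }
  J
}

oracle_ddj <- function(D, J) {
  n <- length(D)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) M[i, j] <- D[i] * D[j] * J[i, j]
  M
}

oracle_nmi <- function(a, b) {
  labs_a <- unique(a); labs_b <- unique(b)
  N <- length(a)
  num <- 0
  for (i in labs_a) {
    for (j in labs_b) {
      cij <- sum(a == i & b == j)
      if (cij > 0) num <- num + cij * log(cij * N / (sum(a == i) * sum(b == j)))
    }
  }
  den <- sum(sapply(labs_a, function(i) sum(a == i) * log(sum(a == i) / N))) +
         sum(sapply(labs_b, function(j) sum(b == j) * log(sum(b == j) / N)))
  if (den == 0) return(1)
  -2 * num / den
}

oracle_f1 <- function(Tsets, Dsets) {
  pair_f1 <- function(t, d) {
    ov <- length(intersect(t, d))
    if (ov == 0L) return(0)
    p <- ov / length(d); r <- ov / length(t)
    2 * p * r / (p + r)
  }
  ft <- sapply(Tsets, function(t) max(sapply(Dsets, function(d) pair_f1(t, d))))
  fd <- sapply(Dsets, function(d) max(sapply(Tsets, function(t) pair_f1(t, d))))
  (mean(ft) + mean(fd)) / 2
}

random_test_graph <- function(n, p = 0.15) igraph::sample_gnp(n, p)

# a random partition into at most k non-degenerate blocks
random_partition <- function(n, k) {
  repeat {
    memb <- sample.int(k, n, replace = TRUE)
    if (length(unique(memb)) >= 2L) return(memb)
  }
}
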