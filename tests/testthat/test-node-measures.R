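# three disjoint triangles with one community each: any node's 2-hop ball
# stays inside its own community
three_triangles <- function() {
  g <- do.call(igraph::disjoint_union,
               replicate(3, igraph::make_full_graph(3), simplify = FALSE))
  list(graph = g, membership = rep(1:3, each = 3))
}

test_that("membership distribution reflects the ball's community split", {
  tt <- three_triangles()
  expect_equal(unname(membership_distribution(tt$graph, 1, 2, tt$membership)),
               c(1, 0, 0))

  # ball split evenly across two communities: an edge between them
  g <- igraph::make_graph(~ 1 - 2)
  expect_equal(unname(membership_distribution(g, 1, 1, c(1, 2))), c(0.5, 0.5))

  # h = 0: indicator of the node's own community
  expect_equal(unname(membership_distribution(tt$graph, 4, 0, tt$membership)),
               c(0, 1, 0))
})

test_that("CB uncertainty is base-2 entropy of the ball distribution", {
  tt <- three_triangles()
  expect_identical(cb_uncertainty(tt$graph, 1, 2, tt$membership), 0)

  g <- igraph::make_graph(~ 1 - 2)
  expect_equal(cb_uncertainty(g, 1, 1, c(1, 2)), 1)

  # star center with 4 leaves in 4 distinct communities, plus the center's own:
  # uniform over 4 needs an explicit 4-block ball
  g4 <- igraph::make_full_graph(4)
  expect_equal(cb_uncertainty(g4, 1, 1, c(1, 2, 3, 4)), 2)
})

test_that("node density matches hand-computed values", {
  k5 <- igraph::make_full_graph(5)
  expect_equal(node_density(k5, 1, 1), 1)

  # path a-b-c at h=1: ends see a 2-node/1-edge ball, middle the whole path
  expect_equal(density_vector(path3(), 1), c(1, 2 / 3, 1))

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(node_density(iso, 2, 1), 0)

  expect_error(node_density(k5, 1, 0), "h must be")
})

test_that("DD score is density times degree", {
  k4 <- igraph::make_full_graph(4)
  expect_equal(dd_score(k4, 1, 1), 3)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(dd_score(star, 1, 1), (4 / 10) * 4)   # 1.6

  iso <- igraph::make_empty_graph(2, directed = FALSE)
  expect_equal(dd_score(iso, 1, 1), 0)
})

test_that("density vector handles disjoint components independently", {
  g <- do.call(igraph::disjoint_union,
               replicate(2, igraph::make_full_graph(3), simplify = FALSE))
  expect_equal(density_vector(g, 1), rep(1, 6))
})

test_that("Jaccard similarity follows open-neighborhood set arithmetic", {
  k3 <- igraph::make_full_graph(3)
  expect_equal(jaccard_similarity(k3, 1, 1), 1)
  expect_equal(jaccard_similarity(k3, 1, 2), 1 / 3)

  # N(a)={1,2,3}, N(b)={2,3,4}: 2 shared of 4 total
  g <- igraph::make_graph(~ a - 1, a - 2, a - 3, b - 2, b - 3, b - 4)
  expect_equal(jaccard_similarity(g, "a", "b"), 0.5)

  # disjoint neighborhoods
  g2 <- igraph::make_graph(~ a - 1, b - 2)
  expect_equal(jaccard_similarity(g2, "a", "b"), 0)
  expect_error(jaccard_similarity(k3, 1, 99), "unknown node")
})

test_that("jaccard_matrix agrees with pairwise brute force on random graphs", {
  k3 <- igraph::make_full_graph(3)
  J3 <- as.matrix(jaccard_matrix(k3))
  expect_equal(unname(J3), matrix(c(1, 1/3, 1/3, 1/3, 1, 1/3, 1/3, 1/3, 1), 3))

  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_equal(unname(as.matrix(jaccard_matrix(empty))), diag(4))

  set.seed(11)
  for (rep in 1:25) {
    g <- random_test_graph(sample(5:30, 1), runif(1, 0.05, 0.4))
    J <- as.matrix(jaccard_matrix(g))
    expect_equal(unname(J), oracle_jaccard_matrix(g), tolerance = 1e-12)
    expect_true(isSymmetric(unname(J)))
    expect_true(all(J >= 0 & J <= 1))
    expect_equal(unname(Matrix::diag(J)), rep(1, igraph::vcount(g)))
  }
})

test_that("DDJ matrix is the density-scaled Hadamard product", {
  set.seed(13)
  g <- random_test_graph(5, 0.6)
  J <- jaccard_matrix(g)
  expect_equal(as.matrix(ddj_matrix(rep(1, 5), J)), as.matrix(J),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(max(abs(ddj_matrix(rep(0, 5), J))), 0)

  D <- runif(5)
  expect_equal(unname(as.matrix(ddj_matrix(D, J))),
               oracle_ddj(D, as.matrix(J)), tolerance = 1e-12)
  expect_error(ddj_matrix(runif(4), J), "dimension mismatch")
})

test_that("density is 1 exactly when the ball induces a clique", {
  set.seed(17)
  for (rep in 1:10) {
    g <- random_test_graph(20, 0.15)
    dens <- density_vector(g, 2)
    expect_true(all(dens >= 0 & dens <= 1))
    for (v in seq_len(20)) {
      ball <- bfs_ball(g, v, 2)
      sub <- induced_ball_subgraph(g, ball)
      is_clique <- length(ball) >= 2 &&
        igraph::ecount(sub) == choose(length(ball), 2)
      expect_equal(dens[v] == 1, is_clique)
    }
  }
})

test_that("bridge nodes have lower density than community-interior nodes", {
  rc <- ring_of_cliques(3, 5)
  dens <- density_vector(rc$graph, 1)
  bridge <- which(igraph::degree(rc$graph) == 5)   # clique-mates + bridge
  interior <- setdiff(seq_len(15), bridge)
  expect_true(max(dens[bridge]) < min(dens[interior]))
})

test_that("node_measures table is internally consistent", {
  g <- two_k5()$graph
  nm <- node_measures(g, h = 2)
  expect_equal(nm$dd, nm$density * nm$degree)
  expect_equal(nm$degree, as.integer(igraph::degree(g)))
})
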