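test_that("jaccard_row_distance is plain Euclidean distance", {
  expect_equal(jaccard_row_distance(c(1, 0), c(1, 0)), 0)
  expect_equal(jaccard_row_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_error(jaccard_row_distance(1:3, 1:2), "lengths differ")

  set.seed(3)
  for (rep in 1:20) {
    a <- runif(6); b <- runif(6); c <- runif(6)
    expect_equal(jaccard_row_distance(a, b), jaccard_row_distance(b, a))
    expect_lte(jaccard_row_distance(a, c),
               jaccard_row_distance(a, b) + jaccard_row_distance(b, c) + 1e-12)
  }
})

test_that("assignment picks the nearest centroid, ties to lowest index", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  J <- jaccard_matrix(g)
  C <- as.matrix(J[c(1, 5), , drop = FALSE])
  memb <- assign_clusters(J, C)
  expect_equal(memb, rep(1:2, each = 4))

  # identical centroids: everything ties to cluster 1
  C2 <- as.matrix(J[c(1, 1), , drop = FALSE])
  expect_equal(unique(assign_clusters(J, C2)), 1L)

  # K = 1
  expect_equal(unique(assign_clusters(J, as.matrix(J[1, , drop = FALSE]))), 1L)
})

test_that("centroid update equals brute-force row averaging", {
  set.seed(21)
  g <- random_test_graph(6, 0.5)
  J <- jaccard_matrix(g)
  memb <- c(1L, 1L, 2L, 2L, 2L, 1L)
  C <- update_centroids(J, memb, 2)
  Jd <- as.matrix(J)
  expect_equal(C[1, ], colMeans(Jd[memb == 1L, ]), ignore_attr = TRUE)
  expect_equal(C[2, ], colMeans(Jd[memb == 2L, ]), ignore_attr = TRUE)

  # singleton cluster keeps its row; identical rows keep the row
  memb2 <- c(1L, rep(2L, 5))
  C2 <- update_centroids(J, memb2, 2)
  expect_equal(C2[1, ], Jd[1, ], ignore_attr = TRUE)
})

test_that("k-means recovers planted cliques from one seed per clique", {
  inst <- two_k5()
  J <- jaccard_matrix(inst$graph)
  res <- kmeans_cluster(J, c(1L, 6L))
  expect_true(res$converged)
  expect_equal(nmi(inst$membership, res$membership), 1)

  res1 <- kmeans_cluster(J, 1L)
  expect_equal(unique(res1$membership), 1L)
  expect_equal(res1$iterations, 1L)

  res0 <- kmeans_cluster(J, c(1L, 6L), max_iter = 0)
  expect_false(res0$converged)
  expect_equal(res0$iterations, 0L)
  expect_equal(nmi(inst$membership, res0$membership), 1)  # initial assignment

  expect_error(kmeans_cluster(J, c(1L, 1L)), "distinct")
  expect_error(kmeans_cluster(J, 1:11), "exceeds")
})

test_that("assignment and update steps never increase the k-means objective", {
  sse <- function(J, C, memb) {
    Jd <- as.matrix(J)
    sum(vapply(seq_len(nrow(Jd)),
               function(i) sum((Jd[i, ] - C[memb[i], ])^2), numeric(1)))
  }
  set.seed(31)
  for (rep in 1:5) {
    inst <- generate_planted_partition(3, 8, 0.7, 0.1, seed = 40 + rep)
    J <- jaccard_matrix(inst$graph)
    seeds <- select_seeds(inst$graph, 3)
    C <- as.matrix(J[seeds, , drop = FALSE])
    memb <- assign_clusters(J, C)
    for (it in 1:8) {
      before <- sse(J, C, memb)
      C <- update_centroids(J, memb, 3)
      mid <- sse(J, C, memb)
      expect_lte(mid, before + 1e-9)
      memb <- assign_clusters(J, C)
      expect_lte(sse(J, C, memb), mid + 1e-9)
    }
  }
})

test_that("ddjkm_detect recovers clean structures deterministically", {
  inst <- two_k5()
  r1 <- ddjkm_detect(inst$graph, 2)
  r2 <- ddjkm_detect(inst$graph, 2)
  expect_identical(r1$membership, r2$membership)
  expect_equal(nmi(inst$membership, r1$membership), 1)
  expect_lte(r1$iterations, 100)

  rc <- ring_of_cliques(4, 5)
  res <- ddjkm_detect(rc$graph, 4)
  expect_equal(nmi(rc$membership, res$membership), 1)

  expect_error(ddjkm_detect(igraph::make_empty_graph(0, directed = FALSE), 1),
               "no nodes")
})

test_that("empty-cluster repair keeps K non-empty communities", {
  # K larger than the natural cluster count forces splits via repair
  inst <- two_k5()
  res <- ddjkm_detect(inst$graph, 4)
  expect_equal(sort(unique(res$membership)), 1:4)
  expect_true(all(tabulate(res$membership, 4) > 0))
})

test_that("random-init k-means is reproducible and labels all K at K = n", {
  inst <- two_k5()
  r1 <- random_init_kmeans(inst$graph, 2, rng_seed = 5)
  r2 <- random_init_kmeans(inst$graph, 2, rng_seed = 5)
  expect_identical(r1$membership, r2$membership)
  expect_identical(r1$seeds, r2$seeds)

  rn <- random_init_kmeans(inst$graph, 10, rng_seed = 5, max_iter = 0)
  expect_equal(sort(unique(rn$membership)), 1:10)  # every node its own cluster
})

test_that("seeded initialization is no worse than random on clean cliques", {
  inst <- two_k5()
  dd_nmi <- nmi(inst$membership, ddjkm_detect(inst$graph, 2)$membership)
  rand_nmi <- vapply(1:20, function(s)
    nmi(inst$membership, random_init_kmeans(inst$graph, 2, s)$membership),
    numeric(1))
  expect_gte(dd_nmi, mean(rand_nmi))
})
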