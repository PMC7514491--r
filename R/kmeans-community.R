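#' Euclidean distance between two Jaccard feature vectors
#'
#' The k-means stage measures node affinity as the Euclidean distance
#' between rows of the Jaccard similarity matrix.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative real.
#' @export
jaccard_row_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vector lengths differ")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

# Squared distances between every row of sparse J (n x n) and every centroid
# (K x n dense): ||x||^2 + ||c||^2 - 2 x.c, clipped at 0.
row_centroid_dist2 <- function(J, C, row_norm2 = NULL) {
  if (is.null(row_norm2)) row_norm2 <- Matrix::rowSums(J^2)
  cn2 <- rowSums(C^2)
  cross <- as.matrix(J %*% t(C))
  d2 <- outer(row_norm2, cn2, "+") - 2 * cross
  d2[d2 < 0] <- 0
  d2
}

#' Assign every node to its nearest centroid
#'
#' Ties (equidistant centroids) go to the lowest cluster index, so the
#' assignment is deterministic.
#'
#' @param J Jaccard similarity matrix (rows are feature vectors).
#' @param C K-by-n centroid matrix.
#' @return Integer membership vector in `1..K`.
#' @export
assign_clusters <- function(J, C) {
  d2 <- row_centroid_dist2(J, C)
  max.col(-d2, ties.method = "first")
}

#' Recompute centroids as cluster row-means
#'
#' Centroid `j` becomes the component-wise mean of the Jaccard rows of the
#' nodes assigned to cluster `j`.
#'
#' @param J Jaccard similarity matrix.
#' @param membership Integer membership vector in `1..K`.
#' @param K Number of clusters.
#' @return K-by-n dense centroid matrix.
#' @export
update_centroids <- function(J, membership, K) {
  n <- nrow(J)
  sizes <- tabulate(membership, nbins = K)
  M <- Matrix::sparseMatrix(i = membership, j = seq_len(n),
                            x = 1 / pmax(sizes[membership], 1),
                            dims = c(K, n))
  as.matrix(M %*% J)
}

#' k-means over Jaccard rows from given initial centers
#'
#' Initial centroids are the Jaccard rows of the seed nodes. Iterates
#' assignment/update until the assignment stops changing, the maximum
#' centroid displacement (MaxDist) falls below `tol`, or `max_iter` is
#' reached. A cluster that empties during iteration is reseeded with the row
#' of the node farthest from its current centroid, keeping exactly K
#' non-empty communities in the output.
#'
#' @param J Jaccard similarity matrix.
#' @param seeds Distinct vertex indices; `length(seeds)` is K.
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence threshold on MaxDist (default 1e-9).
#' @return A list of class `ddjkm_result`: `membership` (integer vector),
#'   `K`, `iterations`, `converged`, `max_dist`, `seeds`.
#' @export
kmeans_cluster <- function(J, seeds, max_iter = 100, tol = 1e-9) {
  n <- nrow(J)
  K <- length(seeds)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (K > n) stop("K exceeds the number of nodes")
  row_norm2 <- Matrix::rowSums(J^2)
  C <- as.matrix(J[seeds, , drop = FALSE])

  memb <- max.col(-row_centroid_dist2(J, C, row_norm2), ties.method = "first")
  iter <- 0L
  converged <- FALSE
  max_dist <- NA_real_

  while (iter < max_iter) {
    iter <- iter + 1L
    memb <- repair_empty(J, C, memb, K, row_norm2)
    C_new <- update_centroids(J, memb, K)
    max_dist <- sqrt(max(rowSums((C_new - C)^2)))
    C <- C_new
    memb_new <- max.col(-row_centroid_dist2(J, C, row_norm2),
                        ties.method = "first")
    if (identical(memb_new, memb) || max_dist < tol) {
      memb <- memb_new
      converged <- TRUE
      break
    }
    memb <- memb_new
  }
  memb <- repair_empty(J, C, memb, K, row_norm2)
  structure(list(membership = memb, K = K, iterations = iter,
                 converged = converged, max_dist = max_dist,
                 seeds = seeds),
            class = "ddjkm_result")
}

# Deterministic empty-cluster repair: each empty cluster is reseeded with the
# node currently farthest from its assigned centroid (largest first).
repair_empty <- function(J, C, memb, K, row_norm2) {
  empty <- setdiff(seq_len(K), unique(memb))
  if (length(empty) == 0L) return(memb)
  d2 <- row_centroid_dist2(J, C, row_norm2)
  own <- d2[cbind(seq_along(memb), memb)]
  for (k in empty) {
    movable <- which(tabulate(memb, nbins = K)[memb] > 1L)
    if (length(movable) == 0L) break
    far <- movable[order(-own[movable], movable)][1L]
    memb[far] <- k
    own[far] <- 0
  }
  memb
}

#' @method print ddjkm_result
#' @export
print.ddjkm_result <- function(x, ...) {
  cat(sprintf("ddjkm clustering: %d communities over %d nodes\n",
              x$K, length(x$membership)))
  cat(sprintf("  iterations: %d (converged: %s, final MaxDist: %.3g)\n",
              x$iterations, x$converged, x$max_dist))
  cat("  community sizes:",
      paste(tabulate(x$membership, nbins = x$K), collapse = " "), "\n")
  invisible(x)
}

#' Detect communities with the density-degree seeded k-means (DDJKM)
#'
#' End-to-end driver: compute node densities and DD scores, build the
#' Jaccard and DDJ matrices, pick K seeds by descending DD with
#' minimum-average-correlation spreading, and run k-means over the Jaccard
#' rows from those seeds. Fully deterministic: repeated calls on the same
#' input give identical partitions.
#'
#' @param g An undirected `igraph` object.
#' @param K Number of communities (a required user input).
#' @param h BFS-ball hop count for node density (default 3).
#' @param max_iter k-means iteration cap (default 100).
#' @param tol Convergence threshold on centroid displacement.
#' @return A `ddjkm_result` (see [kmeans_cluster()]).
#' @examples
#' g <- igraph::disjoint_union(igraph::make_full_graph(5),
#'                             igraph::make_full_graph(5))
#' res <- ddjkm_detect(g, K = 2)
#' table(res$membership)
#' @export
ddjkm_detect <- function(g, K, h = 3, max_iter = 100, tol = 1e-9) {
  if (igraph::vcount(g) == 0L) stop("graph has no nodes")
  dens <- density_vector(g, h)
  J <- jaccard_matrix(g)
  DDJ <- ddj_matrix(dens, J)
  dd <- dens * as.numeric(igraph::degree(g))
  seeds <- select_seeds(g, K, h, DDJ = DDJ, dd = dd)
  kmeans_cluster(J, seeds, max_iter = max_iter, tol = tol)
}

#' k-means community detection with random initial centers
#'
#' The baseline the seeded method is compared against: K distinct nodes are
#' drawn uniformly at random (under `rng_seed`) as initial centers; the
#' clustering stage is identical to [kmeans_cluster()].
#'
#' @param g An undirected `igraph` object.
#' @param K Number of communities.
#' @param rng_seed Integer seed making the draw reproducible.
#' @param max_iter,tol As in [kmeans_cluster()].
#' @return A `ddjkm_result`.
#' @export
random_init_kmeans <- function(g, K, rng_seed, max_iter = 100, tol = 1e-9) {
  n <- igraph::vcount(g)
  if (K > n) stop("K exceeds the number of nodes")
  J <- jaccard_matrix(g)
  seeds <- withr::with_seed(rng_seed, sample.int(n, K))
  kmeans_cluster(J, seeds, max_iter = max_iter, tol = tol)
}
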