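#' Community-membership distribution of a node's BFS ball
#'
#' For node `v`, the fraction of its h-hop BFS ball falling in each community
#' of a partition. This is the distribution whose Shannon entropy defines the
#' community-belongingness (CB) uncertainty of the node.
#'
#' @param g An undirected `igraph` object.
#' @param v Vertex index or name.
#' @param h Non-negative hop count.
#' @param membership Integer membership vector covering all vertices.
#' @return Named numeric probability vector over community labels (sums to 1).
#' @export
membership_distribution <- function(g, v, h, membership) {
  stopifnot(length(membership) == igraph::vcount(g))
  ball <- bfs_ball(g, v, h)
  labs <- sort(unique(as.integer(membership)))
  counts <- tabulate(match(as.integer(membership)[ball], labs),
                     nbins = length(labs))
  setNames(counts / length(ball), labs)
}

#' Community-belongingness uncertainty of a node
#'
#' Shannon entropy (base 2) of [membership_distribution()]. A node whose ball
#' lies entirely in one community has uncertainty 0; a ball spread uniformly
#' over `m` communities has uncertainty `log2(m)`.
#'
#' @inheritParams membership_distribution
#' @return Entropy in bits.
#' @export
cb_uncertainty <- function(g, v, h, membership) {
  p <- membership_distribution(g, v, h, membership)
  p <- p[p > 0]
  -sum(p * log2(p)) + 0   # + 0 avoids IEEE negative zero for degenerate p
}

#' Node density of the h-hop BFS ball
#'
#' With `S` the h-hop ball of `v` and `G'` its induced subgraph, density is
#' `|E'| / (|V'| (|V'|-1) / 2)`: the edge count of `G'` over the maximum
#' possible. Nodes buried inside a single community score high; nodes
#' bridging communities score low. Isolated nodes (ball of size 1) get 0.
#'
#' @param g An undirected `igraph` object.
#' @param v Vertex index or name.
#' @param h Hop count, at least 1.
#' @return Density in `[0, 1]`.
#' @export
node_density <- function(g, v, h = 3) {
  if (h < 1) stop("h must be >= 1")
  v <- as_vertex_index(g, v)
  density_vector(g, h)[v]
}

#' Densities of all nodes in canonical vertex order
#'
#' @param g An undirected `igraph` object.
#' @param h Hop count, at least 1.
#' @return Numeric vector of densities, one per vertex.
#' @export
density_vector <- function(g, h = 3) {
  if (h < 1) stop("h must be >= 1")
  adj0 <- lapply(adjacency_list(g), function(x) x - 1L)
  .density_all_cpp(adj0, as.integer(h))
}

#' Density-degree (DD) score
#'
#' `DD(v) = density(v) * degree(v)`: the seed-ranking criterion balancing
#' degree centrality against community-belongingness certainty. Isolated
#' nodes always score 0.
#'
#' @inheritParams node_density
#' @return Non-negative real.
#' @export
dd_score <- function(g, v, h = 3) {
  v <- as_vertex_index(g, v)
  node_density(g, v, h) * igraph::degree(g)[[v]]
}

dd_vector <- function(g, h = 3) {
  density_vector(g, h) * as.numeric(igraph::degree(g))
}

#' Jaccard similarity of two nodes' neighborhoods
#'
#' Shared-neighbor count over union-neighbor count, using open neighborhoods
#' (a node is not its own neighbor). By convention the self-similarity is 1,
#' and two distinct nodes with empty neighborhoods score 0.
#'
#' @param g An undirected `igraph` object.
#' @param a,b Vertex indices or names.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(g, a, b) {
  a <- as_vertex_index(g, a); b <- as_vertex_index(g, b)
  if (a == b) return(1)
  adj <- adjacency_list(g)
  u <- length(union(adj[[a]], adj[[b]]))
  if (u == 0L) return(0)
  length(intersect(adj[[a]], adj[[b]])) / u
}

#' Jaccard similarity matrix of a graph
#'
#' The n-by-n matrix of pairwise neighborhood Jaccard similarities, stored
#' sparse (most pairs share no neighbor in a sparse graph). Rows double as
#' the feature vectors of the k-means stage. Diagonal entries are 1.
#'
#' @param g An undirected `igraph` object.
#' @return A symmetric `dgCMatrix` with unit diagonal, entries in `[0, 1]`.
#' @export
jaccard_matrix <- function(g) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- as(as(A, "generalMatrix"), "CsparseMatrix") * 1.0
  common <- A %*% A                       # common-neighbor counts
  common <- as(common, "CsparseMatrix")
  deg <- Matrix::rowSums(A)
  # |N(a) u N(b)| = deg(a) + deg(b) - common(a,b), on the nonzero pattern
  trip <- Matrix::summary(common)
  uni <- deg[trip$i] + deg[trip$j] - trip$x
  val <- ifelse(uni > 0, trip$x / uni, 0)
  J <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = val, dims = c(n, n))
  Matrix::diag(J) <- 1
  J <- methods::as(J, "CsparseMatrix")
  dimnames(J) <- list(vertex_labels(g), vertex_labels(g))
  J
}

#' Density-weighted Jaccard correlation (DDJ) matrix
#'
#' Hadamard product of the density outer product with the Jaccard matrix:
#' `DDJ[i, j] = D[i] * D[j] * J[i, j]`. Used during seed selection to keep
#' initial cluster centers mutually dissimilar.
#'
#' @param D Density vector (length n).
#' @param J Jaccard similarity matrix (n-by-n).
#' @return A symmetric non-negative sparse matrix.
#' @export
ddj_matrix <- function(D, J) {
  if (length(D) != nrow(J) || nrow(J) != ncol(J)) {
    stop("dimension mismatch between density vector and Jaccard matrix")
  }
  S <- Matrix::Diagonal(x = as.numeric(D))
  methods::as(S %*% J %*% S, "CsparseMatrix")
}

#' Per-node measure table
#'
#' @param g An undirected `igraph` object.
#' @param h Hop count for the density ball.
#' @return A data.frame with columns `node`, `degree`, `density`, `dd`.
#' @export
node_measures <- function(g, h = 3) {
  dens <- density_vector(g, h)
  deg <- as.integer(igraph::degree(g))
  data.frame(node = vertex_labels(g), degree = deg,
             density = dens, dd = dens * deg,
             stringsAsFactors = FALSE)
}
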