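#' Nodes ordered by descending DD score
#'
#' Sorts all nodes by `density * degree` descending; runs of equal DD are
#' ordered by ascending node id, so the sequence is fully deterministic.
#'
#' @param g An undirected `igraph` object.
#' @param h Hop count for the density ball.
#' @return Integer vector of vertex indices.
#' @export
dd_sequence <- function(g, h = 3) {
  dd <- dd_vector(g, h)
  order(-dd, seq_along(dd))
}

#' Average DDJ correlation of a candidate to the current seed set
#'
#' Mean over the seeds of the DDJ-matrix entry pairing each seed with the
#' candidate. A candidate sharing no weighted neighborhood with any seed
#' scores 0 — the minimum — which is what pushes successive seeds into
#' different communities.
#'
#' @param DDJ Density-weighted Jaccard correlation matrix.
#' @param seeds Non-empty vector of seed vertex indices.
#' @param p Candidate vertex index (not a seed).
#' @return Non-negative real.
#' @export
average_correlation <- function(DDJ, seeds, p) {
  if (length(seeds) == 0L) stop("seed set is empty")
  if (p %in% seeds) stop("candidate is already a seed")
  mean(DDJ[seeds, p])
}

#' Select K initial cluster centers
#'
#' The first seed is the global DD maximum. Each further round computes, for
#' every remaining candidate, its average DDJ correlation to the current
#' seeds; the candidates attaining the minimum average correlation are
#' collected, and the one with maximum DD joins the seed set (remaining ties
#' broken by ascending node id). Candidates with DD = 0 — exactly the
#' isolated nodes — are only considered once every positive-DD node has been
#' used, so isolated nodes are never chosen while a non-isolated candidate
#' remains. The procedure is fully deterministic.
#'
#' @param g An undirected `igraph` object.
#' @param K Number of seeds, `1 <= K <= |V|`.
#' @param h Hop count for the density ball.
#' @param DDJ Optional precomputed DDJ matrix (recomputed otherwise).
#' @param dd Optional precomputed DD vector.
#' @return Integer vector of K distinct vertex indices, in selection order.
#' @export
select_seeds <- function(g, K, h = 3, DDJ = NULL, dd = NULL) {
  n <- igraph::vcount(g)
  if (K < 1L) stop("K must be at least 1")
  if (K > n) stop("K exceeds the number of nodes")
  if (is.null(dd)) dd <- dd_vector(g, h)
  if (is.null(DDJ)) DDJ <- ddj_matrix(density_vector(g, h), jaccard_matrix(g))

  seeds <- integer(0)
  first <- order(-dd, seq_len(n))[1L]
  seeds <- first
  corr_sum <- as.numeric(DDJ[first, ])   # running column sums over seeds

  while (length(seeds) < K) {
    cand <- setdiff(seq_len(n), seeds)
    pos <- cand[dd[cand] > 0]
    pool <- if (length(pos) > 0L) pos else cand
    rp <- corr_sum[pool] / length(seeds)
    minset <- pool[rp == min(rp)]
    nxt <- minset[order(-dd[minset], minset)][1L]
    seeds <- c(seeds, nxt)
    corr_sum <- corr_sum + as.numeric(DDJ[nxt, ])
  }
  seeds
}
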