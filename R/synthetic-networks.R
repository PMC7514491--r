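#' Parameter bundle for the LFR-style benchmark generator
#'
#' Describes a benchmark family by node count `n`, degree power-law exponent
#' `tau1`, community-size power-law exponent `tau2`, community-size bounds
#' `c_min`/`c_max`, target mean degree `k_avg`, maximum degree `k_max`, and
#' mixing parameter `mu` (the fraction of each node's edges that leave its
#' community).
#'
#' @param n Number of nodes.
#' @param tau1 Degree power-law exponent.
#' @param tau2 Community-size power-law exponent.
#' @param c_min,c_max Community-size bounds.
#' @param k_avg Target mean degree.
#' @param k_max Maximum degree.
#' @param mu Mixing parameter in `[0, 1]`.
#' @return A list of class `lfr_params`.
#' @export
lfr_params <- function(n, tau1 = 2, tau2 = 1, c_min, c_max, k_avg, k_max, mu) {
  stopifnot(mu >= 0, mu <= 1, c_min <= c_max, c_max <= n,
            k_avg <= k_max, k_max < n, k_avg >= 1)
  structure(list(n = as.integer(n), tau1 = tau1, tau2 = tau2,
                 c_min = as.integer(c_min), c_max = as.integer(c_max),
                 k_avg = k_avg, k_max = as.integer(k_max), mu = mu),
            class = "lfr_params")
}

# Smallest-degree cutoff whose truncated power law on [kmin, kmax] has mean
# closest to the target (integer scan; the discrete analogue of solving for
# kmin numerically).
solve_kmin <- function(tau1, k_max, k_avg) {
  means <- vapply(seq_len(k_max), function(kmin) {
    k <- kmin:k_max
    w <- k^(-tau1)
    sum(k * w) / sum(w)
  }, numeric(1))
  which.min(abs(means - k_avg))
}

sample_power_law <- function(m, exponent, lo, hi) {
  v <- lo:hi
  sample(v, m, replace = TRUE, prob = v^(-exponent))
}

# Community sizes from the truncated power law, tiled to sum exactly to n.
draw_community_sizes <- function(n, tau2, c_min, c_max, max_tries = 200) {
  for (try in seq_len(max_tries)) {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample_power_law(1L, tau2, c_min, c_max))
    }
    excess <- sum(sizes) - n
    last <- sizes[length(sizes)]
    if (excess == 0L) return(sizes)
    if (last - excess >= c_min) {
      sizes[length(sizes)] <- last - excess
      return(sizes)
    }
    # spread the excess over communities with room to shrink
    sizes <- sizes[-length(sizes)]
    deficit <- n - sum(sizes)
    room <- which(sizes < c_max)
    while (deficit > 0L && length(room) > 0L) {
      take <- room[seq_len(min(deficit, length(room)))]
      sizes[take] <- sizes[take] + 1L
      deficit <- n - sum(sizes)
      room <- which(sizes < c_max)
    }
    if (deficit == 0L && all(sizes >= c_min & sizes <= c_max)) return(sizes)
  }
  stop("could not tile community sizes to n within bounds; ",
       "parameters may be infeasible")
}

# Pair up stubs into simple edges: shuffle, pair consecutively, keep good
# pairs, reshuffle the stubs of bad ones (self-loops, duplicates, and pairs
# failing `ok_pair`). Stubs still unplaced after `passes` passes are paired
# greedily against any remaining compatible partner; only stubs with no
# compatible partner at all are dropped.
match_stubs <- function(stubs, n, forbidden_keys = integer(0),
                        ok_pair = NULL, passes = 40L) {
  edges_u <- integer(0); edges_v <- integer(0)
  seen <- as.numeric(forbidden_keys)
  for (pass in seq_len(passes)) {
    m <- length(stubs)
    if (m < 2L) break
    if (m %% 2L == 1L) stubs <- stubs[-m]
    stubs <- sample(stubs)
    u <- stubs[c(TRUE, FALSE)]
    v <- stubs[c(FALSE, TRUE)]
    lo <- pmin(u, v); hi <- pmax(u, v)
    key <- as.numeric(lo) * (n + 1) + hi
    good <- lo != hi & !(key %in% seen) & !duplicated(key)
    if (!is.null(ok_pair)) good <- good & ok_pair(lo, hi)
    edges_u <- c(edges_u, lo[good]); edges_v <- c(edges_v, hi[good])
    seen <- c(seen, key[good])
    stubs <- c(lo[!good], hi[!good])
  }
  if (length(stubs) >= 2L) {
    rem <- sort(stubs)
    while (length(rem) >= 2L) {
      u <- rem[1L]
      rem <- rem[-1L]
      cand <- unique(rem[rem != u])
      if (!is.null(ok_pair) && length(cand) > 0L) {
        cand <- cand[ok_pair(pmin(u, cand), pmax(u, cand))]
      }
      if (length(cand) > 0L) {
        key <- as.numeric(pmin(u, cand)) * (n + 1) + pmax(u, cand)
        cand <- cand[!(key %in% seen)]
      }
      if (length(cand) == 0L) next           # no partner: drop this stub
      v <- sample(cand, 1L)
      rem <- rem[-match(v, rem)]
      edges_u <- c(edges_u, min(u, v)); edges_v <- c(edges_v, max(u, v))
      seen <- c(seen, as.numeric(min(u, v)) * (n + 1) + max(u, v))
    }
  }
  cbind(edges_u, edges_v)
}

# Realize a community's internal degree sequence exactly where possible:
# Viger-Latapy sampling first, then the heuristic simple-graph sampler, and
# only then stub matching (which may drop a few stubs).
community_edges <- function(members, kint, n) {
  keep <- kint > 0L
  members <- members[keep]; kint <- kint[keep]
  if (sum(kint) < 2L) return(matrix(integer(0), ncol = 2L))
  gc <- tryCatch(suppressWarnings(igraph::sample_degseq(kint, method = "vl")),
                 error = function(e) NULL)
  if (is.null(gc)) {
    gc <- tryCatch(
      suppressWarnings(igraph::sample_degseq(kint, method = "fast.heur.simple")),
      error = function(e) NULL)
  }
  if (!is.null(gc)) {
    el <- igraph::as_edgelist(gc, names = FALSE)
    return(cbind(members[el[, 1L]], members[el[, 2L]]))
  }
  match_stubs(rep(members, kint), n)
}

#' Generate an LFR-style benchmark network
#'
#' Emulates the LFR benchmark construction: node degrees follow a truncated
#' power law with exponent `tau1` (the lower cutoff is solved so the mean
#' matches `k_avg`), community sizes follow a truncated power law with
#' exponent `tau2` on `[c_min, c_max]` and tile `n` exactly, and each node
#' places a fraction `1 - mu` of its edges inside its community and `mu`
#' outside. Edges are realized by within-community and between-community
#' stub matching with bounded rewiring; the handful of stubs that cannot be
#' placed without self-loops or duplicates are dropped, so realized degrees
#' can fall slightly below their targets. Exact edge-level equivalence with
#' the reference LFR program is not claimed; the realized mixing and mean
#' degree are reported alongside the planted partition.
#'
#' @param params An [lfr_params()] bundle.
#' @param seed Integer RNG seed; fixed seed gives identical instances.
#' @return A list of class `benchmark_instance`: `graph` (igraph),
#'   `membership` (planted partition), `K`, `realized_mu`,
#'   `realized_mean_degree`, `params`.
#' @examples
#' inst <- generate_lfr(lfr_params(n = 300, c_min = 10, c_max = 30,
#'                                 k_avg = 8, k_max = 20, mu = 0.1),
#'                      seed = 1)
#' inst$K
#' @export
generate_lfr <- function(params, seed) {
  stopifnot(inherits(params, "lfr_params"))
  withr::with_seed(as.integer(seed), generate_lfr_impl(params))
}

generate_lfr_impl <- function(p) {
  n <- p$n
  kmin <- solve_kmin(p$tau1, p$k_max, p$k_avg)

  deg <- NULL
  for (try in seq_len(50L)) {
    cand <- sample_power_law(n, p$tau1, kmin, p$k_max)
    if (abs(mean(cand) - p$k_avg) <= 0.1 * p$k_avg) { deg <- cand; break }
  }
  if (is.null(deg)) stop("could not realize mean degree within 10% of target")
  if (sum(deg) %% 2L == 1L) {
    i <- which(deg < p$k_max)[1L]
    deg[i] <- deg[i] + 1L
  }

  sizes <- draw_community_sizes(n, p$tau2, p$c_min, p$c_max)
  K <- length(sizes)

  k_int <- as.integer(round((1 - p$mu) * deg))
  # assign nodes to communities, largest internal degree first, each into a
  # random community that still has a free slot and is big enough
  memb <- integer(n)
  free <- sizes
  for (v in order(-k_int, seq_len(n))) {
    ok <- which(free > 0L & sizes - 1L >= k_int[v])
    if (length(ok) == 0L) {
      ok <- which(free > 0L)
      big <- ok[sizes[ok] == max(sizes[ok])]
      com <- if (length(big) > 1L) sample(big, 1L) else big
      k_int[v] <- sizes[com] - 1L            # cap: can't exceed clique-mates
    } else {
      com <- if (length(ok) > 1L) sample(ok, 1L) else ok
    }
    memb[v] <- com
    free[com] <- free[com] - 1L
  }
  k_ext <- deg - k_int

  # within-community internal-stub parity
  for (c_id in seq_len(K)) {
    members <- which(memb == c_id)
    if (sum(k_int[members]) %% 2L == 1L) {
      up <- members[k_int[members] < sizes[c_id] - 1L & k_ext[members] > 0L]
      if (length(up) > 0L) {
        v <- up[1L]; k_int[v] <- k_int[v] + 1L; k_ext[v] <- k_ext[v] - 1L
      } else {
        # no external stub to borrow (e.g. mu = 0): drop one internal stub
        # instead of inventing an inter-community edge
        v <- members[which(k_int[members] > 0L)[1L]]
        k_int[v] <- k_int[v] - 1L
      }
    }
  }

  edges <- matrix(integer(0), ncol = 2L)
  for (c_id in seq_len(K)) {
    members <- which(memb == c_id)
    edges <- rbind(edges, community_edges(members, k_int[members], n))
  }

  ext_stubs <- rep(seq_len(n), k_ext)
  if (length(ext_stubs) >= 2L) {
    lo <- pmin(edges[, 1L], edges[, 2L]); hi <- pmax(edges[, 1L], edges[, 2L])
    internal_keys <- as.numeric(lo) * (n + 1) + hi
    edges <- rbind(edges,
                   match_stubs(ext_stubs, n, forbidden_keys = internal_keys,
                               ok_pair = function(a, b) memb[a] != memb[b]))
  }

  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  g <- igraph::simplify(g)
  new_benchmark_instance(g, memb, "lfr", p)
}

new_benchmark_instance <- function(g, memb, generator, params) {
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ext_deg <- tabulate(c(el[, 1L][memb[el[, 1L]] != memb[el[, 2L]]],
                        el[, 2L][memb[el[, 1L]] != memb[el[, 2L]]]),
                      nbins = igraph::vcount(g))
  mix <- ifelse(deg > 0, ext_deg / deg, 0)
  structure(list(graph = g, membership = as.integer(memb),
                 K = length(unique(memb)),
                 realized_mu = mean(mix[deg > 0]),
                 realized_mean_degree = mean(deg),
                 generator = generator, params = params),
            class = "benchmark_instance")
}

#' @method print benchmark_instance
#' @export
print.benchmark_instance <- function(x, ...) {
  cat(sprintf("%s benchmark: %d nodes, %d edges, %d planted communities\n",
              x$generator, igraph::vcount(x$graph),
              igraph::ecount(x$graph), x$K))
  cat(sprintf("  realized mean degree %.2f, realized mixing %.3f\n",
              x$realized_mean_degree, x$realized_mu))
  invisible(x)
}

#' Generate a planted-partition (equal-block SBM) network
#'
#' Independent Bernoulli edges with probability `p_in` within each of
#' `blocks` equal blocks and `p_out` between blocks; the block structure is
#' attached as the planted partition. A small controllable surrogate for the
#' LFR benchmark in unit tests.
#'
#' @param blocks Number of blocks.
#' @param block_size Nodes per block.
#' @param p_in,p_out Within/between-block edge probabilities
#'   (`p_out <= p_in`).
#' @param seed Integer RNG seed.
#' @return A `benchmark_instance`.
#' @export
generate_planted_partition <- function(blocks, block_size, p_in, p_out, seed) {
  stopifnot(p_out >= 0, p_in <= 1, p_out <= p_in)
  n <- blocks * block_size
  memb <- rep(seq_len(blocks), each = block_size)
  pref <- matrix(p_out, blocks, blocks)
  diag(pref) <- p_in
  g <- withr::with_seed(as.integer(seed),
                        igraph::sample_sbm(n, pref.matrix = pref,
                                           block.sizes = rep(block_size, blocks)))
  new_benchmark_instance(g, memb,
                         "planted-partition",
                         list(blocks = blocks, block_size = block_size,
                              p_in = p_in, p_out = p_out))
}

#' Ring of cliques
#'
#' `c` cliques of size `s`, consecutive cliques joined by exactly one
#' bridging edge (the last node of each clique to the first node of the
#' next, wrapping around). A deterministic fixture in which bridge endpoints
#' have strictly lower ball density than their clique-mates.
#'
#' @param c_cliques Number of cliques (at least 2).
#' @param s Clique size (at least 3).
#' @return A `benchmark_instance` whose planted partition is the cliques.
#' @export
ring_of_cliques <- function(c_cliques, s) {
  stopifnot(c_cliques >= 2L, s >= 3L)
  n <- c_cliques * s
  blocks <- split(seq_len(n), rep(seq_len(c_cliques), each = s))
  clique_edges <- do.call(rbind, lapply(blocks, function(b) t(utils::combn(b, 2L))))
  last <- vapply(blocks, max, integer(1))
  first <- vapply(blocks, min, integer(1))
  bridges <- cbind(last, first[c(seq_len(c_cliques)[-1L], 1L)])
  g <- igraph::graph_from_edgelist(rbind(clique_edges, bridges),
                                   directed = FALSE)
  new_benchmark_instance(g, rep(seq_len(c_cliques), each = s),
                         "ring-of-cliques",
                         list(c_cliques = c_cliques, s = s))
}

#' Disjoint cliques
#'
#' `c` cliques of size `s` with no edges between them; the sharpest possible
#' community structure.
#'
#' @inheritParams ring_of_cliques
#' @return A `benchmark_instance`.
#' @export
disjoint_cliques <- function(c_cliques, s) {
  stopifnot(c_cliques >= 1L, s >= 2L)
  g <- do.call(igraph::disjoint_union,
               replicate(c_cliques, igraph::make_full_graph(s),
                         simplify = FALSE))
  new_benchmark_instance(g, rep(seq_len(c_cliques), each = s),
                         "disjoint-cliques",
                         list(c_cliques = c_cliques, s = s))
}
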