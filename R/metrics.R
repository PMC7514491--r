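#' Confusion matrix of two partitions
#'
#' Entry `(i, j)` counts the nodes in community `i` of `A` that are also in
#' community `j` of `B`. Row sums are `A`'s community sizes, column sums are
#' `B`'s, and the grand total is the number of nodes.
#'
#' @param a,b Membership vectors over the same node set (same length and,
#'   when named, the same names).
#' @return Integer matrix with community labels as dimnames.
#' @export
confusion_matrix <- function(a, b) {
  check_same_nodes(a, b)
  unclass(table(A = a, B = b))
}

check_same_nodes <- function(a, b) {
  if (length(a) != length(b)) stop("partitions cover different node sets")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("partitions cover different node sets")
    }
  }
  invisible(TRUE)
}

#' Normalized mutual information of two partitions
#'
#' `NMI = 2 I(A; B) / (H(A) + H(B))` computed from the confusion matrix;
#' 1 when the partitions are identical up to relabeling, 0 when they are
#' independent. The log base cancels (natural log used internally) and
#' `0 log 0` is treated as 0. When both partitions are a single block the
#' normalizer vanishes; the value is defined as 1 (the partitions are then
#' necessarily identical) with a warning.
#'
#' @param a,b Membership vectors over the same node set. When both carry
#'   names, `b` is aligned to `a`'s node order first.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  check_same_nodes(a, b)
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  C <- confusion_matrix(a, b)
  N <- sum(C)
  ri <- rowSums(C)
  cj <- colSums(C)
  denom <- sum(ri * log(ri / N)) + sum(cj * log(cj / N))
  if (denom == 0) {
    warning("both partitions are a single block; NMI defined as 1")
    return(1)
  }
  nz <- C > 0
  num <- sum(C[nz] * log(C[nz] * N / outer(ri, cj)[nz]))
  -2 * num / denom
}

#' Bidirectional best-match F1 between community collections
#'
#' For each ground-truth community the best harmonic mean of precision and
#' recall over the detected communities is found; the score is the average
#' of the two directional means (truth to detected and detected to truth).
#' Pairs with empty overlap contribute 0. Accepts either membership vectors
#' (converted to community node-sets) or lists of node-id vectors, so it
#' applies to both disjoint partitions and overlapping ground-truth
#' collections.
#'
#' @param truth,detected Membership vectors or lists of node-id vectors.
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(truth, detected) {
  T_ <- as_community_sets(truth)
  D_ <- as_community_sets(detected)
  if (length(T_) == 0L || length(D_) == 0L) stop("empty community collection")
  overlap <- vapply(T_, function(t)
    vapply(D_, function(d) length(intersect(t, d)), numeric(1)),
    numeric(length(D_)))
  overlap <- matrix(overlap, nrow = length(D_))   # D x T
  sz_t <- lengths(T_)
  sz_d <- lengths(D_)
  f1 <- 2 * overlap / outer(sz_d, sz_t, "+")      # pairwise harmonic means
  (mean(apply(f1, 2L, max)) + mean(apply(f1, 1L, max))) / 2
}

as_community_sets <- function(x) {
  if (is.list(x)) return(x)
  ids <- if (!is.null(names(x))) names(x) else seq_along(x)
  split(ids, x)
}
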