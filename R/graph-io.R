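#' @useDynLib ddjkm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats sd setNames
#' @importFrom utils read.table write.table
NULL

# Normalize a raw igraph object to the package's graph contract:
# undirected, simple, with a persisted label -> vertex-index table in the
# "name" attribute. All-numeric labels are ordered numerically so that
# tie-breaks on "ascending node id" match the input's own numbering.
normalize_graph <- function(g, warn_dropped = TRUE) {
  if (igraph::is_directed(g)) {
    stop("directed graphs are not supported; provide an undirected graph")
  }
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (warn_dropped && (n_loops > 0L || n_multi > 0L)) {
    warning(sprintf("dropped %d self-loop(s) and %d parallel edge(s)",
                    n_loops, n_multi))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (!is.null(igraph::V(g)$name)) {
    labs <- igraph::V(g)$name
    num <- suppressWarnings(as.numeric(labs))
    ord <- if (!anyNA(num)) order(num) else order(labs)
    g <- igraph::permute(g, order(ord))
  }
  g
}

#' Read an undirected graph from a whitespace-delimited edge list
#'
#' Each non-comment line holds two node labels; `#` starts a comment.
#' Self-loops and duplicate edges are dropped (with a warning giving counts)
#' so the result is always a simple undirected graph. Numeric labels are
#' ordered numerically; vertex order defines the canonical node order used by
#' all matrix-valued measures.
#'
#' @param path Path to the edge-list file.
#' @return An undirected simple `igraph` object.
#' @examples
#' tf <- tempfile()
#' writeLines(c("1 2", "2 3"), tf)
#' g <- read_edge_list(tf)
#' igraph::vcount(g)
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  if (length(body) == 0L) stop("empty edge list: ", path)
  toks <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list line %d: '%s'",
                 which(keep)[bad[1L]], body[bad[1L]]))
  }
  el <- matrix(unlist(toks), ncol = 2L, byrow = TRUE)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  normalize_graph(g)
}

#' Read an undirected graph from a GML file
#'
#' Accepts the standard node/edge block dialect (the format in which the
#' classic dolphins/polbooks/football benchmark graphs circulate). Directed
#' GML files are rejected. GML `id` fields become node labels; duplicate edge
#' records are dropped.
#'
#' @param path Path to the GML file.
#' @return An undirected simple `igraph` object.
#' @export
read_gml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("directed\\s+1", txt)) {
    stop("GML declares a directed graph; only undirected graphs are supported")
  }
  g <- igraph::read_graph(path, format = "gml")
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id)) {
    igraph::V(g)$name <- as.character(igraph::V(g)$id)
  }
  normalize_graph(g)
}

#' Write a graph as an edge list
#'
#' Inverse of [read_edge_list()]: node labels (or vertex indices when the
#' graph is unnamed) are written one edge per line.
#'
#' @param g An undirected `igraph` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L]), path)
  invisible(path)
}

#' Read a partition from a two-column node/label table
#'
#' @param path TSV/whitespace-delimited file with columns `node_id`
#'   `community_label` (no header).
#' @param g Optional graph; when given, the partition is checked to cover
#'   exactly its vertex set and is returned in the graph's vertex order.
#' @return An integer membership vector (community labels recoded to
#'   `1..K`), named by node label.
#' @export
read_partition <- function(path, g = NULL) {
  tab <- read.table(path, header = FALSE, col.names = c("node", "label"),
                    colClasses = "character")
  if (anyDuplicated(tab$node)) stop("duplicate node ids in partition file")
  memb <- setNames(as.integer(factor(tab$label)), tab$node)
  if (!is.null(g)) {
    vn <- vertex_labels(g)
    if (!setequal(names(memb), vn)) {
      stop("partition file does not cover the graph's node set")
    }
    memb <- memb[vn]
  }
  memb
}

#' Write a partition as a two-column node/label table
#'
#' @param membership Membership vector in vertex order (names used as node
#'   ids when present).
#' @param path Output path.
#' @param g Optional graph supplying node labels.
#' @return `path`, invisibly.
#' @export
write_partition <- function(membership, path, g = NULL) {
  nodes <- if (!is.null(g)) vertex_labels(g)
           else if (!is.null(names(membership))) names(membership)
           else seq_along(membership)
  write.table(data.frame(node = nodes, community = as.integer(membership)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Node labels in canonical vertex order (indices when the graph is unnamed).
vertex_labels <- function(g) {
  if (!is.null(igraph::V(g)$name)) igraph::V(g)$name
  else as.character(seq_len(igraph::vcount(g)))
}

#' Nodes within h hops of a start node
#'
#' The h-hop BFS ball: the start node plus every node at shortest-path
#' distance at most `h` from it.
#'
#' @param g An undirected `igraph` object.
#' @param v Vertex index or name.
#' @param h Non-negative hop count.
#' @return Integer vector of vertex indices (always contains `v`).
#' @export
bfs_ball <- function(g, v, h) {
  if (h < 0) stop("h must be non-negative")
  v <- as_vertex_index(g, v)
  ball <- igraph::ego(g, order = h, nodes = v)[[1L]]
  sort(as.integer(ball))
}

#' Subgraph induced by a node set
#'
#' @param g An undirected `igraph` object.
#' @param S Vertex indices or names; must all belong to `g`.
#' @return The induced subgraph (all edges of `g` with both endpoints in `S`).
#' @export
induced_ball_subgraph <- function(g, S) {
  S <- vapply(S, function(v) as_vertex_index(g, v), integer(1L))
  igraph::induced_subgraph(g, S)
}

as_vertex_index <- function(g, v) {
  n <- igraph::vcount(g)
  if (is.character(v)) {
    idx <- match(v, vertex_labels(g))
    if (is.na(idx)) stop("unknown node: ", v)
    return(as.integer(idx))
  }
  v <- as.integer(v)
  if (is.na(v) || v < 1L || v > n) stop("unknown node: ", v)
  v
}

# Adjacency as a plain list of integer vectors, 1-based, in vertex order.
adjacency_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}
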