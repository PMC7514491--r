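# Small deterministic fixtures shared across test files.

path3 <- function() igraph::make_graph(~ a - b, b - c)

two_k5 <- function() disjoint_cliques(2, 5)

# two 5-cliques plus isolated vertices
two_k5_plus_isolated <- function(n_iso = 3) {
  inst <- two_k5()
  g <- igraph::add_vertices(inst$graph, n_iso)
  list(graph = g, n_iso = n_iso,
       isolated = igraph::vcount(inst$graph) + seq_len(n_iso))
}

# canonical "lo|hi" edge keys for set comparison
vertex_pairs <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  apply(el, 1L, function(e) paste(sort(e), collapse = "|"))
}

write_tmp_lines <- function(lines) {
  tf <- tempfile(fileext = ".txt")
  writeLines(lines, tf)
  tf
}

minimal_gml <- function(directed = FALSE, dup_edge = FALSE) {
  lines <- c("graph [",
             if (directed) "  directed 1",
             "  node [ id 1 ]",
             "  node [ id 2 ]",
             "  edge [ source 1 target 2 ]",
             if (dup_edge) "  edge [ source 2 target 1 ]",
             "]")
  write_tmp_lines(lines)
}

# The mixing-parameter sweep used by the benchmark-ordering and monotone-
# degradation checks; computed once and cached across test files.
.sweep_cache <- new.env(parent = emptyenv())
lfr1_sweep <- function() {
  if (is.null(.sweep_cache$res)) {
    .sweep_cache$res <- run_benchmark(
      lfr_family("lfr1"), mu_values = seq(0.1, 0.9, by = 0.1),
      replicates = 10, seed = 1)
  }
  .sweep_cache$res
}
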