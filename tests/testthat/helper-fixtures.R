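# Small in-code fixtures.

rec <- function(id, group, ...) fluency_record(id, group, c(...))

# Tiny two-group cohort with known set algebra.
tiny_cohort <- function() {
  list(
    a = list(rec("a1", "M", "cat", "dog", "fox"),
             rec("a2", "M", "cat", "dog"),
             rec("a3", "M", "cat", "owl", "fox")),
    b = list(rec("b1", "T", "cat", "dog"),
             rec("b2", "T", "dog", "hen"),
             rec("b3", "T", "cat", "dog", "hen")))
}

# Deterministic small response matrix from 0/1 rows.
rmat <- function(rows, exemplars, group = "G") {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sprintf("p%d", seq_along(rows)), exemplars)
  response_matrix(m, group)
}

# Named small graphs used by closed-form metric checks.
graph_k <- function(n) igraph::make_full_graph(n)
graph_star3 <- function() igraph::make_star(4, mode = "undirected")
graph_path3 <- function() igraph::make_graph(~ a - b, b - c)
graph_k4_minus_edge <- function() {
  igraph::delete_edges(igraph::make_full_graph(4), 1)
}
two_triangles_bridge <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d, c - d)
}
two_triangles_disjoint <- function() {
  igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
}

fast_config <- function(seed = 1L, ...) {
  analysis_config(iters_bootstrap = 20L, iters_null = 20L,
                  louvain_restarts = 20L, louvain_restarts_resample = 5L,
                  seed = seed, ...)
}
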