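# Network measures: clustering coefficient, average shortest path length,
# modularity. By default all three are computed on the unweighted
# (binarized) graph — path length is defined in steps (edges) — with
# weighted variants (Barrat CC, inverse-weight distances) available for
# sensitivity analysis.

#' Mean local clustering coefficient
#'
#' Watts-Strogatz mean of the local clustering coefficient over all nodes:
#' the local CC of a node is the number of edges among its neighbors
#' divided by the number possible; nodes of degree < 2 contribute 0.
#'
#' @param net an igraph network.
#' @param weighted if TRUE, use the Barrat weighted local coefficient.
#' @return the mean local clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(net, weighted = FALSE) {
  g <- strip_network_class(net)
  if (weighted) {
    local <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  } else {
    local <- igraph::transitivity(as_unweighted(g), type = "local",
                                  isolates = "zero")
  }
  local[is.na(local)] <- 0
  mean(local)
}

#' Average shortest path length
#'
#' Mean over all unordered node pairs of the shortest-path length. By
#' default distances are hop counts (each edge is one step); the weighted
#' variant uses inverse edge weights as lengths, so strong associations
#' are short.
#'
#' @param net a connected igraph network with >= 2 nodes.
#' @param weighted if TRUE, use inverse-weight edge lengths.
#' @return the ASPL (>= 1 for unweighted connected graphs).
#' @export
average_shortest_path_length <- function(net, weighted = FALSE) {
  g <- strip_network_class(net)
  if (!igraph::is_connected(g)) {
    stop_stage("metrics", "graph is disconnected; ASPL undefined")
  }
  if (weighted) {
    igraph::mean_distance(g, weights = 1 / igraph::E(g)$weight)
  } else {
    igraph::mean_distance(g, weights = NA)
  }
}

#' Newman-Girvan modularity of a given partition
#'
#' Computes
#' \deqn{Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]}
#' where, for community c, \eqn{e_c} is the (weight of) edges inside c,
#' \eqn{d_c} the total (strength) degree of its nodes, and m the total
#' edge count (weight). Does not require connectivity.
#'
#' @param net an igraph network.
#' @param membership integer community label per vertex.
#' @param weighted use edge weights.
#' @return the modularity Q in \[-0.5, 1\].
#' @export
partition_modularity <- function(net, membership, weighted = FALSE) {
  g <- strip_network_class(net)
  membership <- as.integer(as.factor(membership))
  stopifnot(length(membership) == igraph::vcount(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if (weighted) igraph::E(g)$weight else rep(1, nrow(el))
  m <- sum(w)
  if (m == 0) stop_stage("metrics", "graph has no edges; Q undefined")
  comms <- sort(unique(membership))
  e_c <- vapply(comms, function(c0) {
    sum(w[membership[el[, 1]] == c0 & membership[el[, 2]] == c0])
  }, 0)
  d_c <- vapply(comms, function(c0) {
    sum(w[membership[el[, 1]] == c0]) + sum(w[membership[el[, 2]] == c0])
  }, 0)
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Modularity of the best-found Louvain partition
#'
#' Runs Louvain community detection `restarts` times under randomized node
#' orders (seeded, hence reproducible) and returns the partition with the
#' largest Newman-Girvan modularity
#' \deqn{Q = \sum_c \left[ e_c/m - (d_c/2m)^2 \right]}
#' over communities c, where m is the edge count, e_c the number of edges
#' inside c, and d_c the total degree of c.
#'
#' @param net a connected igraph network.
#' @param seed integer seed for the restart streams.
#' @param restarts number of seeded Louvain runs (default 100).
#' @param weighted if TRUE, use edge weights in Louvain and Q.
#' @return list with `q`, `membership` (named integer vector) and
#'   `n_communities`.
#' @export
modularity_q <- function(net, seed = 1L, restarts = 100L, weighted = FALSE) {
  g <- strip_network_class(net)
  if (!weighted) g <- as_unweighted(g)
  n <- igraph::vcount(g)
  best_q <- -Inf
  best_m <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      gp <- igraph::permute(g, perm)
      wp <- if (weighted) igraph::E(gp)$weight else NULL
      cl <- igraph::cluster_louvain(gp, weights = wp)
      memb <- igraph::membership(cl)[perm]   # back to original vertex order
      q <- partition_modularity(g, memb, weighted = weighted)
      if (q > best_q) {
        best_q <- q
        best_m <- memb
      }
    }
  })
  names(best_m) <- igraph::V(g)$name
  list(q = best_q, membership = best_m,
       n_communities = length(unique(best_m)))
}

#' All three network measures
#'
#' @param net a connected igraph network.
#' @param seed seed for the Louvain restarts.
#' @param restarts Louvain restarts.
#' @param weighted compute weighted variants of all three measures.
#' @return list of class `network_metrics`: `group`, `n_nodes`, `n_edges`,
#'   `cc`, `aspl`, `q`, `n_communities`, `seed`.
#' @export
network_metrics <- function(net, seed = 1L, restarts = 100L,
                            weighted = FALSE) {
  qres <- modularity_q(net, seed = seed, restarts = restarts,
                       weighted = weighted)
  structure(list(
    group = if (igraph::is_igraph(net))
      tryCatch(igraph::graph_attr(net, "group"), error = function(e) NA) else NA,
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    cc = clustering_coefficient(net, weighted = weighted),
    aspl = average_shortest_path_length(net, weighted = weighted),
    q = qres$q,
    n_communities = qres$n_communities,
    seed = seed), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "<network_metrics> group %s: n=%d, m=%d | CC=%.4f ASPL=%.4f Q=%.4f (%d communities)\n",
    x$group %||% "?", x$n_nodes, x$n_edges, x$cc, x$aspl, x$q,
    x$n_communities))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param metrics a `network_metrics` object.
#' @param path output path.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(unclass(metrics), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

as_unweighted <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "weight")
  }
  g
}
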