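# Triangulated maximally filtered graph (TMFG).
#
# Greedy planar filter: seed with the 4-clique of largest total association,
# then repeatedly insert the remaining node with the largest 3-edge gain
# into a triangular face, splitting that face into three. The result is a
# maximal planar graph with exactly 3n - 6 edges that keeps the largest
# associations. Ties break on the lexicographically smallest node label,
# then the earliest-created face, so the construction is deterministic.

#' Triangulated maximally filtered graph of an association matrix
#'
#' Filters a symmetric nonnegative association matrix down to a connected
#' planar graph with exactly `3n - 6` edges (n = number of nodes), keeping
#' the strongest associations via greedy triangular-face insertion.
#'
#' @param assoc symmetric numeric matrix with nonnegative entries and
#'   dimnames (e.g. from [cosine_association()]); the diagonal is ignored.
#' @param group optional group label attached to the result; defaults to
#'   the matrix's `"group"` attribute.
#' @return an undirected weighted [igraph::graph] of class
#'   `semantic_network` (subclass of `igraph`), edge weights copied from
#'   `assoc`, with graph attributes `group` and `method = "tmfg"`.
#' @export
tmfg <- function(assoc, group = attr(assoc, "group")) {
  W <- unclass(assoc)
  n <- nrow(W)
  if (is.null(colnames(W))) colnames(W) <- rownames(W) <- sprintf("v%03d", seq_len(n))
  labels <- colnames(W)
  if (n < 4L) stop_stage("tmfg", "need at least 4 nodes, got %d", n)
  if (!isSymmetric(unname(W), tol = 1e-10)) {
    stop_stage("tmfg", "association matrix must be symmetric")
  }
  if (any(W < 0)) stop_stage("tmfg", "association values must be nonnegative")
  diag(W) <- 0
  if (all(W == 0)) stop_stage("tmfg", "association matrix is all zero")

  # Seed clique: 4 nodes with greatest total association; ties to the
  # lexicographically smallest labels (order() below is stable on labels).
  strength <- rowSums(W)
  seed <- order(-strength, labels)[1:4]
  in_net <- rep(FALSE, n)
  in_net[seed] <- TRUE

  edges <- matrix(0L, nrow = 3L * n - 6L, ncol = 2L)
  pairs <- utils::combn(sort(seed), 2L)
  n_edges <- 6L
  edges[1:6, ] <- t(pairs)

  # Triangular faces in creation order; a split face is retired but keeps
  # its index (earliest-created tie-breaking), so allocate room for every
  # face ever created: 4 + 3(n - 4).
  max_faces <- max(4L, 3L * n - 8L)
  faces <- matrix(0L, nrow = max_faces, ncol = 3L)
  s <- sort(seed)
  faces[1:4, ] <- rbind(s[c(1, 2, 3)], s[c(1, 2, 4)], s[c(1, 3, 4)], s[c(2, 3, 4)])
  n_faces <- 4L
  face_alive <- c(rep(TRUE, 4L), rep(FALSE, max_faces - 4L))

  # gains[v, f] = W[v,a] + W[v,b] + W[v,c] for face f = {a,b,c};
  # rows of inserted nodes are set to -Inf.
  gains <- matrix(-Inf, nrow = n, ncol = max_faces)
  out <- which(!in_net)
  for (f in 1:4) {
    gains[out, f] <- W[out, faces[f, 1]] + W[out, faces[f, 2]] + W[out, faces[f, 3]]
  }

  while (any(!in_net)) {
    # Rows of inserted nodes and columns of retired faces sit at -Inf, so
    # the maximum ranges over exactly the open (node, face) pairs.
    best <- max(gains)
    idx <- which(gains == best)
    if (length(idx) > 1L) {
      # Tie-break: smallest node label, then earliest-created face.
      v_cand <- ((idx - 1L) %% n) + 1L
      f_cand <- ((idx - 1L) %/% n) + 1L
      idx <- idx[order(labels[v_cand], f_cand)][1L]
    }
    v <- ((idx - 1L) %% n) + 1L
    f <- ((idx - 1L) %/% n) + 1L
    abc <- faces[f, ]

    edges[n_edges + 1:3, ] <- cbind(rep(v, 3L), abc)
    n_edges <- n_edges + 3L
    in_net[v] <- TRUE
    gains[v, ] <- -Inf
    face_alive[f] <- FALSE
    gains[, f] <- -Inf

    out <- which(!in_net)
    new_faces <- rbind(c(abc[1], abc[2], v), c(abc[1], abc[3], v),
                       c(abc[2], abc[3], v))
    for (k in 1:3) {
      n_faces <- n_faces + 1L
      faces[n_faces, ] <- new_faces[k, ]
      face_alive[n_faces] <- TRUE
      if (length(out)) {
        gains[out, n_faces] <- W[out, new_faces[k, 1]] +
          W[out, new_faces[k, 2]] + W[out, new_faces[k, 3]]
      }
    }
  }

  el <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$name <- labels[seq_len(igraph::vcount(g))]
  # vcount can be < n only if some label index never appeared; impossible
  # here since all nodes are inserted.
  igraph::E(g)$weight <- W[el]
  g <- igraph::set_graph_attr(g, "group", group %||% NA_character_)
  g <- igraph::set_graph_attr(g, "method", "tmfg")
  class(g) <- c("semantic_network", class(g))
  g
}

#' Export a semantic network
#'
#' Writes a weighted undirected network as GraphML and/or a 3-column
#' edge-list CSV (`source,target,weight`).
#'
#' @param net an igraph network (e.g. from [tmfg()]).
#' @param graphml optional output path for GraphML.
#' @param edgelist optional output path for the edge-list CSV.
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, graphml = NULL, edgelist = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(strip_network_class(net), graphml, format = "graphml")
  }
  if (!is.null(edgelist)) {
    el <- igraph::as_edgelist(net)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     weight = igraph::E(net)$weight)
    write.csv(df, edgelist, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(c(graphml = graphml, edgelist = edgelist))
}

#' Read a semantic network from GraphML or an edge-list CSV
#'
#' @param path file path; format inferred from the extension (`.graphml`
#'   vs `.csv`).
#' @return an undirected weighted igraph object.
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
  }
  g
}

# igraph operations dispatch on class(g)[1]; drop our subclass tag first.
strip_network_class <- function(net) {
  class(net) <- "igraph"
  net
}

#' @export
print.semantic_network <- function(x, ...) {
  cat(sprintf("<semantic_network> group %s: %d nodes, %d edges (TMFG)\n",
              igraph::graph_attr(x, "group"),
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}
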