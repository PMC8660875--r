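# Independent oracles used across tests. Each deliberately avoids the code
# path it checks: Floyd-Warshall for ASPL, exhaustive set-partition search
# for modularity, stepwise exhaustive gain maximization for TMFG, and
# networkx (via the system python) for planarity.

# All-pairs hop-count ASPL by Floyd-Warshall on the adjacency matrix.
fw_aspl <- function(g) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  mean(D[upper.tri(D)])
}

# Enumerate all set partitions of 1..n as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) {
      rec(c(prefix, v), max(maxv, v))
    }
  }
  rec(integer(), 0L)
  out
}

# Exhaustive-search maximum modularity over every partition (n <= 8).
max_q_exhaustive <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  qs <- vapply(parts, function(p) igraph::modularity(g, p), 0)
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# Independent TMFG: at every step enumerate all (uninserted node, live
# face) pairs and take the max-gain insertion, with the same tie-break
# rule (smallest label, earliest face). Plain lists, no incremental gain
# bookkeeping.
tmfg_bruteforce <- function(W) {
  n <- nrow(W)
  labels <- colnames(W)
  diag(W) <- 0
  strength <- rowSums(W)
  seed <- sort(order(-strength, labels)[1:4])
  edges <- t(utils::combn(seed, 2))
  faces <- list(seed[c(1, 2, 3)], seed[c(1, 2, 4)], seed[c(1, 3, 4)],
                seed[c(2, 3, 4)])
  alive <- rep(TRUE, 4)
  remaining <- setdiff(seq_len(n), seed)
  while (length(remaining)) {
    best <- NULL
    for (v in remaining[order(labels[remaining])]) {
      for (fi in seq_along(faces)) {
        if (!alive[fi]) next
        gain <- sum(W[v, faces[[fi]]])
        if (is.null(best) || gain > best$gain + 1e-12) {
          best <- list(v = v, fi = fi, gain = gain)
        }
      }
    }
    abc <- faces[[best$fi]]
    edges <- rbind(edges, cbind(best$v, abc))
    alive[best$fi] <- FALSE
    faces <- c(faces, list(c(abc[1], abc[2], best$v)),
               list(c(abc[1], abc[3], best$v)),
               list(c(abc[2], abc[3], best$v)))
    alive <- c(alive, TRUE, TRUE, TRUE)
    remaining <- setdiff(remaining, best$v)
  }
  # canonical edge set as "i-j" strings with i < j
  sort(paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]),
             sep = "-"))
}

edge_key <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}

# Planarity of one or more graphs via networkx, one python process for
# the whole batch. Returns a logical vector.
check_planarity_networkx <- function(graphs) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  stopifnot(nzchar(py))
  inp <- tempfile(fileext = ".txt")
  lines <- vapply(graphs, function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    paste(paste(el[, 1], el[, 2], sep = ","), collapse = ";")
  }, "")
  writeLines(lines, inp)
  script <- paste(
    "import sys, networkx as nx",
    "for line in open(sys.argv[1]):",
    "    g = nx.Graph()",
    "    for tok in line.strip().split(';'):",
    "        a, b = tok.split(',')",
    "        g.add_edge(int(a), int(b))",
    "    print(int(nx.check_planarity(g)[0]))",
    sep = "\n")
  out <- system2(py, c("-c", shQuote(script), inp), stdout = TRUE)
  as.integer(out) == 1L
}

# Symmetric association matrix with positive off-diagonal entries.
random_assoc <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n, 0.01, 1), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  rownames(A) <- colnames(A) <- sprintf("w%03d", seq_len(n))
  A
}
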