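# Erdos-Renyi null ensembles and percentile p values.

#' Simulate an Erdos-Renyi null ensemble of network measures
#'
#' Draws `iters` random graphs matched in scale to an empirical network —
#' either G(n, p) with a fixed edge probability p = m / C(n, 2) (default,
#' so the expected edge count matches) or G(n, m) with exactly m edges —
#' and computes CC, ASPL and Q for each. ASPL of a disconnected draw is
#' computed on its largest connected component.
#'
#' @param n node count (>= 4).
#' @param m edge count (0 < m <= n(n-1)/2).
#' @param iters number of random graphs (default 1000).
#' @param seed integer master seed.
#' @param model `"gnp"` (fixed edge probability) or `"gnm"` (fixed edge
#'   count).
#' @param restarts Louvain restarts per draw (smaller than for the
#'   empirical network: the ensemble averages over draws).
#' @return a list of three `metric_distribution` objects named `cc`,
#'   `aspl`, `q`, plus `edges`, the realized edge count of every draw
#'   (constant and equal to m under `"gnm"`; binomial with mean m under
#'   `"gnp"`). Each distribution carries the values, `iters`, `seed` and
#'   provenance.
#' @export
simulate_er_ensemble <- function(n, m, iters = 1000L, seed = 1L,
                                 model = c("gnp", "gnm"), restarts = 10L) {
  model <- match.arg(model)
  stopifnot(n >= 4L, m > 0L, m <= n * (n - 1) / 2, iters >= 1L)
  p <- m / (n * (n - 1) / 2)
  seeds <- spawn_seeds(seed, iters)
  vals <- matrix(NA_real_, nrow = iters, ncol = 3L,
                 dimnames = list(NULL, c("cc", "aspl", "q")))
  n_edges <- integer(iters)
  for (i in seq_len(iters)) {
    g <- with_seed(seeds[i], {
      if (model == "gnp") igraph::sample_gnp(n, p) else igraph::sample_gnm(n, m)
    })
    n_edges[i] <- igraph::ecount(g)
    vals[i, "cc"] <- clustering_coefficient(g)
    comp <- igraph::largest_component(g)
    vals[i, "aspl"] <- if (igraph::vcount(comp) >= 2L) {
      average_shortest_path_length(comp)
    } else NA_real_
    vals[i, "q"] <- if (igraph::ecount(g) > 0L) {
      modularity_q(g, seed = seeds[i], restarts = restarts)$q
    } else NA_real_
  }
  out <- lapply(c(cc = "cc", aspl = "aspl", q = "q"), function(me) {
    metric_distribution(me, vals[, me], seed = seed,
                        provenance = "random_ensemble",
                        model = model, n_nodes = n, n_edges = m)
  })
  out$edges <- n_edges
  out
}

#' A distribution of simulated network-measure values
#'
#' @param measure one of `"cc"`, `"aspl"`, `"q"`.
#' @param values numeric vector of simulated values.
#' @param seed master seed that produced the values.
#' @param provenance `"random_ensemble"` or `"bootstrap"`.
#' @param ... further provenance fields stored as attributes.
#' @return numeric vector of class `metric_distribution`.
#' @export
metric_distribution <- function(measure, values, seed,
                                provenance = c("random_ensemble", "bootstrap"),
                                ...) {
  provenance <- match.arg(provenance)
  structure(as.numeric(values), measure = measure, iters = length(values),
            seed = seed, provenance = provenance, ...,
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("<metric_distribution> %s (%s): %d values, mean %.4f, sd %.4f\n",
              attr(x, "measure"), attr(x, "provenance"), attr(x, "iters"),
              mean(x, na.rm = TRUE), sd(x, na.rm = TRUE)))
  invisible(x)
}

#' Two-sided percentile p value against a null distribution
#'
#' Add-one (permutation-style) counting:
#' p = 2 min(1 + #\{values <= x\}, 1 + #\{values >= x\}) / (iters + 1),
#' capped at 1, so p is never exactly 0; the smallest attainable p with
#' `iters` simulations is 2 / (iters + 1).
#'
#' @param empirical the empirical measure value.
#' @param dist a `metric_distribution` (or numeric vector) of null values.
#' @return the two-sided p value in (0, 1\].
#' @export
percentile_p_value <- function(empirical, dist) {
  v <- as.numeric(dist)
  v <- v[is.finite(v)]
  stopifnot(length(v) >= 1L)
  lo <- 1L + sum(v <= empirical)
  hi <- 1L + sum(v >= empirical)
  min(1, 2 * min(lo, hi) / (length(v) + 1L))
}

#' Compare empirical measures to a random-graph null ensemble
#'
#' @param metrics a `network_metrics` object for the empirical network.
#' @param ensemble output of [simulate_er_ensemble()] matched to the
#'   network's n and m.
#' @return a data frame with one row per measure: empirical value, null
#'   mean/sd, two-sided p, iterations, and the attainable p floor.
#' @export
null_comparison <- function(metrics, ensemble) {
  rows <- lapply(c("cc", "aspl", "q"), function(me) {
    d <- ensemble[[me]]
    iters <- attr(d, "iters")
    data.frame(measure = me,
               empirical = metrics[[me]],
               null_mean = mean(d, na.rm = TRUE),
               null_sd = sd(d, na.rm = TRUE),
               p_two_sided = percentile_p_value(metrics[[me]], d),
               p_floor = 2 / (iters + 1),
               iters = iters,
               model = attr(d, "model") %||% NA_character_,
               seed = attr(d, "seed"))
  })
  do.call(rbind, rows)
}
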