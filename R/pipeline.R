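# End-to-end orchestration: the semnet_compare() fit, its S3 methods, the
# analysis configuration, and the file-writing report bundle.

#' Analysis configuration
#'
#' Collects every tunable of the group-comparison pipeline. Can be read
#' from a YAML file with [read_analysis_config()].
#'
#' @param min_count minimum-occurrence filter (exemplars must be produced
#'   by at least this many participants in a group).
#' @param iters_bootstrap case-wise bootstrap iterations.
#' @param iters_null Erdos-Renyi null-ensemble draws.
#' @param null_model `"gnp"` or `"gnm"`.
#' @param louvain_restarts Louvain restarts for the empirical networks.
#' @param louvain_restarts_resample Louvain restarts inside bootstrap and
#'   null iterations (smaller: those estimates are averaged over many
#'   draws).
#' @param weighted_metrics compute weighted variants of CC/ASPL/Q.
#' @param equate_per_iteration re-equate nodes inside each bootstrap
#'   iteration (default) or fix the full-sample node set.
#' @param seed master seed for every stochastic stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(min_count = 2L, iters_bootstrap = 1000L,
                            iters_null = 1000L,
                            null_model = c("gnp", "gnm"),
                            louvain_restarts = 100L,
                            louvain_restarts_resample = 10L,
                            weighted_metrics = FALSE,
                            equate_per_iteration = TRUE, seed = 1L) {
  null_model <- match.arg(null_model)
  stopifnot(min_count >= 1L, iters_bootstrap >= 2L, iters_null >= 1L,
            louvain_restarts >= 1L, louvain_restarts_resample >= 1L)
  structure(list(min_count = as.integer(min_count),
                 iters_bootstrap = as.integer(iters_bootstrap),
                 iters_null = as.integer(iters_null),
                 null_model = null_model,
                 louvain_restarts = as.integer(louvain_restarts),
                 louvain_restarts_resample =
                   as.integer(louvain_restarts_resample),
                 weighted_metrics = isTRUE(weighted_metrics),
                 equate_per_iteration = isTRUE(equate_per_iteration),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [analysis_config()] defaults. Overrides passed as `...` win over the
#' file.
#'
#' @param path YAML file path.
#' @param ... named overrides.
#' @return an `analysis_config`.
#' @export
read_analysis_config <- function(path, ...) {
  vals <- yaml::read_yaml(path) %||% list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop_stage("config", "unknown configuration key(s): %s",
               paste(bad, collapse = ", "))
  }
  do.call(analysis_config, vals)
}

#' Estimate and compare two groups' semantic networks
#'
#' The central fitting function. Takes fluency records (or a transcript
#' data frame / CSV path) holding exactly two group labels, and runs the
#' full analysis: normalization, binary response matrices, descriptives,
#' minimum-occurrence filtering, cross-group node equating, cosine
#' association, TMFG filtering, CC/ASPL/Q, Erdos-Renyi null comparison of
#' each group's network, case-wise bootstrap, and independent-group
#' t tests on the bootstrap distributions.
#'
#' @param data a list of `fluency_record`s, a data frame with columns
#'   `participant_id,group,rank,response`, or a path to such a CSV.
#' @param rules a `normalization_rules` object.
#' @param config an [analysis_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `semnet_comparison`; see
#'   [print.semnet_comparison()], [summary.semnet_comparison()],
#'   [plot.semnet_comparison()].
#' @examples
#' coh <- study_cohorts(seed = 42)
#' fit <- semnet_compare(c(coh$records_a, coh$records_b),
#'                       config = analysis_config(iters_bootstrap = 25,
#'                                                iters_null = 25,
#'                                                louvain_restarts = 10,
#'                                                seed = 42))
#' fit
#' @export
semnet_compare <- function(data, rules = normalization_rules(),
                           config = analysis_config(), quiet = FALSE) {
  records <- if (is.character(data) && length(data) == 1L) {
    read_fluency(data)
  } else if (is.data.frame(data)) {
    records_from_frame(data)
  } else data
  stopifnot(all(vapply(records, inherits, TRUE, "fluency_record")))
  groups <- sort(unique(vapply(records, `[[`, "", "group")))
  if (length(groups) != 2L) {
    stop_stage("pipeline", "need exactly two group labels, got: %s",
               paste(groups, collapse = ", "))
  }
  note <- function(...) if (!quiet) flunet_log(...)

  note("normalizing %d records", length(records))
  records <- normalize_cohort(records, rules, quiet = quiet)
  by_group <- split(records, vapply(records, `[[`, "", "group"))
  mat_a <- build_response_matrix(by_group[[groups[1]]])
  mat_b <- build_response_matrix(by_group[[groups[2]]])
  descr <- fluency_descriptives(mat_a, mat_b)

  note("estimating group networks (min_count = %d)", config$min_count)
  est <- estimate_pair(mat_a, mat_b, min_count = config$min_count,
                       seed = config$seed,
                       restarts = config$louvain_restarts,
                       weighted = config$weighted_metrics)

  n <- igraph::vcount(est$net_a)
  m <- igraph::ecount(est$net_a)
  note("null ensembles: %d x G(%d, %d) [%s]", config$iters_null, n, m,
       config$null_model)
  seeds <- spawn_seeds(config$seed, 3L)
  ens_a <- simulate_er_ensemble(n, m, iters = config$iters_null,
                                seed = seeds[1], model = config$null_model,
                                restarts = config$louvain_restarts_resample)
  ens_b <- simulate_er_ensemble(igraph::vcount(est$net_b),
                                igraph::ecount(est$net_b),
                                iters = config$iters_null,
                                seed = seeds[2], model = config$null_model,
                                restarts = config$louvain_restarts_resample)
  nulls <- list(a = null_comparison(est$metrics_a, ens_a),
                b = null_comparison(est$metrics_b, ens_b))

  note("case-wise bootstrap: %d iterations", config$iters_bootstrap)
  boot <- casewise_bootstrap(
    mat_a, mat_b, iters = config$iters_bootstrap, seed = seeds[3],
    min_count = config$min_count,
    restarts = config$louvain_restarts_resample,
    weighted = config$weighted_metrics,
    equate_per_iteration = config$equate_per_iteration)
  comparisons <- compare_bootstrap(boot)

  structure(list(groups = groups,
                 config = config,
                 matrices = list(a = mat_a, b = mat_b),
                 descriptives = descr,
                 networks = list(a = est$net_a, b = est$net_b),
                 metrics = list(a = est$metrics_a, b = est$metrics_b),
                 nulls = nulls,
                 bootstrap = boot,
                 comparisons = comparisons),
            class = "semnet_comparison")
}

#' @export
print.semnet_comparison <- function(x, ...) {
  cat("Group semantic network comparison\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d)\n",
              x$groups[1], nrow(x$matrices$a),
              x$groups[2], nrow(x$matrices$b)))
  cat(sprintf("  equated network: %d nodes, %d edges (TMFG, 3n - 6)\n",
              x$metrics$a$n_nodes, x$metrics$a$n_edges))
  cat("\nEmpirical measures:\n")
  for (g in c("a", "b")) {
    mm <- x$metrics[[g]]
    cat(sprintf("  %s: CC = %.4f, ASPL = %.4f, Q = %.4f (%d communities)\n",
                x$groups[match(g, c("a", "b"))], mm$cc, mm$aspl, mm$q,
                mm$n_communities))
  }
  cat(sprintf("\nBootstrap comparisons (%s minus %s, %d iterations):\n",
              x$groups[1], x$groups[2], x$bootstrap$iters))
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf("  %-4s t(%d) = %7.2f, p %s, d = %5.2f (%s)\n",
                cmp$measure[i], cmp$df[i], cmp$t[i],
                format_p(cmp$p[i]), cmp$d[i], cmp$effect[i]))
  }
  invisible(x)
}

format_p <- function(p, floor = NULL) {
  if (!is.null(floor) && p <= floor) sprintf("< %.3g", floor)
  else if (p < 0.001) "< 0.001"
  else sprintf("= %.3f", p)
}

#' Summary of a semantic network comparison
#'
#' @param object a `semnet_comparison`.
#' @param ... unused.
#' @return the object, invisibly, after printing the descriptives, the
#'   null-model comparisons (with the attainable p floor) and the
#'   bootstrap comparison table.
#' @export
summary.semnet_comparison <- function(object, ...) {
  x <- object
  print(x)
  cat("\nFluency descriptives:\n")
  for (d in x$descriptives) {
    cat(sprintf("  %s: n = %d, responses %.1f (SD %.1f), %d distinct, %d exclusive\n",
                d$group, d$n, d$mean_responses, d$sd_responses,
                d$n_distinct, d$n_exclusive))
  }
  cat("\nRandom-network null comparison (per group):\n")
  for (g in c("a", "b")) {
    nc <- x$nulls[[g]]
    for (i in seq_len(nrow(nc))) {
      cat(sprintf("  %s %-4s empirical %.4f vs null %.4f (SD %.4f), p %s (floor %.4g)\n",
                  x$groups[match(g, c("a", "b"))], nc$measure[i],
                  nc$empirical[i], nc$null_mean[i], nc$null_sd[i],
                  format_p(nc$p_two_sided[i], nc$p_floor[i]), nc$p_floor[i]))
    }
  }
  invisible(x)
}

#' Plot bootstrap measure distributions
#'
#' Side-by-side boxplots of the case-wise bootstrap distributions of CC,
#' ASPL and Q for the two groups.
#'
#' @param x a `semnet_comparison`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.semnet_comparison <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (me in c("cc", "aspl", "q")) {
    graphics::boxplot(
      setNames(list(as.numeric(x$bootstrap$a[[me]]),
                    as.numeric(x$bootstrap$b[[me]])), x$groups),
      main = toupper(me), ylab = me, ...)
  }
  invisible(x)
}

#' Run the full group comparison and write the report bundle
#'
#' Runs [semnet_compare()] and writes, under `out_dir`: a GraphML and
#' edge-list export per group, a metrics JSON per group, the null-model
#' comparison JSON, the bootstrap distributions CSV, the comparison
#' report JSON, and a run log with all seeds and package versions.
#'
#' @param data transcripts as in [semnet_compare()].
#' @param out_dir output directory (created if absent).
#' @param rules a `normalization_rules`.
#' @param config an [analysis_config()].
#' @param quiet suppress progress messages.
#' @return the `semnet_comparison` object, invisibly.
#' @export
run_group_comparison <- function(data, out_dir, rules = normalization_rules(),
                                 config = analysis_config(), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- semnet_compare(data, rules = rules, config = config, quiet = quiet)
  g1 <- fit$groups[1]; g2 <- fit$groups[2]
  write_network(fit$networks$a,
                graphml = file.path(out_dir, paste0("network_", g1, ".graphml")),
                edgelist = file.path(out_dir, paste0("network_", g1, ".csv")))
  write_network(fit$networks$b,
                graphml = file.path(out_dir, paste0("network_", g2, ".graphml")),
                edgelist = file.path(out_dir, paste0("network_", g2, ".csv")))
  write_metrics(fit$metrics$a, file.path(out_dir, paste0("metrics_", g1, ".json")))
  write_metrics(fit$metrics$b, file.path(out_dir, paste0("metrics_", g2, ".json")))
  jsonlite::write_json(list(a = fit$nulls$a, b = fit$nulls$b),
                       file.path(out_dir, "null_comparison.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_bootstrap(fit$bootstrap, file.path(out_dir, "bootstrap.csv"))
  jsonlite::write_json(fit$comparisons,
                       file.path(out_dir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log <- list(timestamp = format(Sys.time(), tz = "UTC"),
              r_version = R.version.string,
              flunet_version =
                as.character(utils::packageVersion("flunet")),
              igraph_version = as.character(utils::packageVersion("igraph")),
              config = unclass(fit$config),
              groups = fit$groups,
              n_nodes = fit$metrics$a$n_nodes,
              n_edges = fit$metrics$a$n_edges,
              bootstrap_redraws = fit$bootstrap$n_redraws)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
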