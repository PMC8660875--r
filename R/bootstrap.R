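# Case-wise participant bootstrap of group networks and the
# independent-group comparison of the resulting measure distributions.

# One full estimation pass on a pair of (already normalized) group
# matrices: per-group min-occurrence filter, cross-group node equating,
# cosine association, TMFG, and the three measures.
estimate_pair <- function(mat_a, mat_b, min_count = 2L, seed = 1L,
                          restarts = 10L, weighted = FALSE,
                          equate = TRUE) {
  fa <- filter_min_occurrence(mat_a, min_count)
  fb <- filter_min_occurrence(mat_b, min_count)
  if (equate) {
    eq <- equate_nodes(fa, fb)
    fa <- eq$a
    fb <- eq$b
  }
  if (ncol(fa) < 4L) {
    stop_stage("estimation", "fewer than 4 shared exemplars (%d)", ncol(fa))
  }
  net_a <- tmfg(cosine_association(fa))
  net_b <- tmfg(cosine_association(fb))
  list(net_a = net_a, net_b = net_b,
       metrics_a = network_metrics(net_a, seed = seed, restarts = restarts,
                                   weighted = weighted),
       metrics_b = network_metrics(net_b, seed = seed + 1L,
                                   restarts = restarts, weighted = weighted))
}

#' Case-wise bootstrap of two groups' network measures
#'
#' In each iteration, each group's participants are resampled with
#' replacement to the original group size, the full estimation pipeline
#' (min-occurrence filter, node equating across the two resampled groups,
#' cosine association, TMFG) is re-run, and CC, ASPL and Q are recorded.
#' Iterations where estimation fails (e.g. an empty node intersection) are
#' redrawn; the redraw count is logged.
#'
#' By default node equating is re-applied within every iteration (the fully
#' case-wise reading); `equate_per_iteration = FALSE` instead fixes the node
#' set from the full-sample estimation and restricts every resample to it.
#'
#' @param mat_a,mat_b raw (pre-filter) `response_matrix` objects.
#' @param iters bootstrap iterations (default 1000).
#' @param seed integer master seed; each iteration and group gets its own
#'   derived substream.
#' @param min_count minimum occurrence filter applied in each iteration.
#' @param restarts Louvain restarts per bootstrap network.
#' @param weighted compute weighted measure variants.
#' @param equate_per_iteration re-equate nodes within each iteration
#'   (default TRUE).
#' @param max_redraws budget of replacement draws for failed iterations.
#' @return list with elements `a` and `b`, each a list of three
#'   `metric_distribution` objects (`cc`, `aspl`, `q`), plus `iters`,
#'   `seed` and `n_redraws`.
#' @export
casewise_bootstrap <- function(mat_a, mat_b, iters = 1000L, seed = 1L,
                               min_count = 2L, restarts = 10L,
                               weighted = FALSE,
                               equate_per_iteration = TRUE,
                               max_redraws = 100L) {
  stopifnot(iters >= 2L)
  fixed_nodes <- NULL
  if (!equate_per_iteration) {
    eq <- equate_nodes(filter_min_occurrence(mat_a, min_count),
                       filter_min_occurrence(mat_b, min_count))
    fixed_nodes <- colnames(eq$a)
  }
  seeds <- spawn_seeds(seed, iters + max_redraws)
  vals_a <- matrix(NA_real_, iters, 3, dimnames = list(NULL, c("cc", "aspl", "q")))
  vals_b <- vals_a
  n_redraws <- 0L
  i <- 1L
  k <- 0L
  while (i <= iters) {
    k <- k + 1L
    if (k > iters + max_redraws) {
      stop_stage("bootstrap", "redraw budget exhausted after %d failures",
                 n_redraws)
    }
    it_seed <- seeds[k]
    res <- tryCatch({
      boot <- with_seed(it_seed, {
        ra <- sample.int(nrow(mat_a), nrow(mat_a), replace = TRUE)
        rb <- sample.int(nrow(mat_b), nrow(mat_b), replace = TRUE)
        list(ra = ra, rb = rb)
      })
      ba <- resample_matrix(mat_a, boot$ra)
      bb <- resample_matrix(mat_b, boot$rb)
      if (!is.null(fixed_nodes)) {
        ba <- restrict_columns(ba, fixed_nodes)
        bb <- restrict_columns(bb, fixed_nodes)
        suppressMessages(
          estimate_pair(ba, bb, min_count = 1L, seed = it_seed,
                        restarts = restarts, weighted = weighted,
                        equate = TRUE))
      } else {
        suppressMessages(
          estimate_pair(ba, bb, min_count = min_count, seed = it_seed,
                        restarts = restarts, weighted = weighted))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_redraws <- n_redraws + 1L
      next
    }
    vals_a[i, ] <- c(res$metrics_a$cc, res$metrics_a$aspl, res$metrics_a$q)
    vals_b[i, ] <- c(res$metrics_b$cc, res$metrics_b$aspl, res$metrics_b$q)
    i <- i + 1L
  }
  if (n_redraws > 0L) {
    flunet_log("bootstrap: %d failed iteration(s) redrawn", n_redraws)
  }
  pack <- function(v) {
    lapply(c(cc = "cc", aspl = "aspl", q = "q"), function(me) {
      metric_distribution(me, v[, me], seed = seed, provenance = "bootstrap")
    })
  }
  list(a = pack(vals_a), b = pack(vals_b), iters = iters, seed = seed,
       n_redraws = n_redraws,
       group_a = attr(mat_a, "group"), group_b = attr(mat_b, "group"))
}

resample_matrix <- function(mat, idx) {
  m <- unclass(mat)[idx, , drop = FALSE]
  rownames(m) <- sprintf("%s.b%03d", rownames(m), seq_along(idx))
  response_matrix(m, attr(mat, "group"))
}

restrict_columns <- function(mat, cols) {
  keep <- intersect(cols, colnames(mat))
  if (length(keep) == 0L) stop_stage("bootstrap", "no fixed nodes present")
  response_matrix(unclass(mat)[, keep, drop = FALSE], attr(mat, "group"))
}

#' Independent-group comparison of two measure distributions
#'
#' Student (pooled-variance) t test on the two bootstrap distributions of
#' one measure, with df = n_a + n_b - 2, plus Cohen's d from the pooled SD.
#' d carries the sign of t; the magnitude is benchmarked as small (0.20),
#' moderate (0.50) or large (0.80).
#'
#' @param dist_a,dist_b `metric_distribution` objects for the same measure.
#' @return a one-row data frame of class `comparison_result` with the
#'   measure, group summaries, t, df, p, d and the effect-size label.
#' @export
compare_distributions <- function(dist_a, dist_b) {
  ma <- attr(dist_a, "measure")
  mb <- attr(dist_b, "measure")
  if (!identical(ma, mb)) {
    stop_stage("bootstrap", "distributions measure different things (%s vs %s)",
               ma, mb)
  }
  a <- as.numeric(dist_a)
  b <- as.numeric(dist_b)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  res <- t_from_raw(a, b, var_equal = TRUE)
  out <- data.frame(measure = ma %||% NA_character_,
                    mean_a = mean(a), sd_a = sd(a),
                    mean_b = mean(b), sd_b = sd(b),
                    t = res$t, df = res$df, p = res$p, d = res$d,
                    effect = effect_label(res$d))
  class(out) <- c("comparison_result", "data.frame")
  out
}

effect_label <- function(d) {
  ad <- abs(d)
  if (ad < 0.20) "negligible"
  else if (ad < 0.50) "small"
  else if (ad < 0.80) "moderate"
  else "large"
}

#' Compare all three bootstrap measure distributions
#'
#' @param boot output of [casewise_bootstrap()].
#' @return a data frame with one `comparison_result` row per measure.
#' @export
compare_bootstrap <- function(boot) {
  out <- do.call(rbind, lapply(c("cc", "aspl", "q"), function(me) {
    compare_distributions(boot$a[[me]], boot$b[[me]])
  }))
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' Write bootstrap distributions as CSV
#'
#' Long format: one row per iteration and group, columns
#' `group,iteration,cc,aspl,q`.
#'
#' @param boot output of [casewise_bootstrap()].
#' @param path output path.
#' @export
write_bootstrap <- function(boot, path) {
  df <- rbind(
    data.frame(group = boot$group_a, iteration = seq_len(boot$iters),
               cc = as.numeric(boot$a$cc), aspl = as.numeric(boot$a$aspl),
               q = as.numeric(boot$a$q)),
    data.frame(group = boot$group_b, iteration = seq_len(boot$iters),
               cc = as.numeric(boot$b$cc), aspl = as.numeric(boot$b$aspl),
               q = as.numeric(boot$b$q)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
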