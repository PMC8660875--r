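# Synthetic cohorts: planted-partition ground truths and censored random
# walks.

test_that("degenerate planted-partition settings give complete graphs", {
  g <- generate_ground_truth(ground_truth_config(
    n_concepts = 12, n_modules = 1, p_in = 1, p_out = 0, seed = 1))
  expect_equal(igraph::ecount(g), choose(12, 2))
  g2 <- generate_ground_truth(ground_truth_config(
    n_concepts = 12, n_modules = 3, p_in = 1, p_out = 0.999999, seed = 1))
  expect_equal(igraph::ecount(g2), choose(12, 2))
})

test_that("ground-truth graphs are connected with labeled modules", {
  g <- generate_ground_truth(ground_truth_config(seed = 2))
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::vcount(g), 120)
  expect_equal(sort(unique(igraph::V(g)$module)), 1:6)
  expect_error(generate_ground_truth(
    ground_truth_config(n_concepts = 60, n_modules = 6, p_in = 0.02,
                        p_out = 0, seed = 3), max_tries = 3),
    "connected")
})

test_that("edge counts match the planted-partition expectation", {
  cfg <- ground_truth_config(n_concepts = 60, n_modules = 4, p_in = 0.5,
                             p_out = 0.15)
  counts <- vapply(1:60, function(s) {
    g <- generate_ground_truth(ground_truth_config(
      n_concepts = 60, n_modules = 4, p_in = 0.5, p_out = 0.15, seed = s))
    igraph::ecount(g)
  }, 0)
  within <- 4 * choose(15, 2)
  between <- choose(60, 2) - within
  expected <- within * 0.5 + between * 0.15
  se <- sqrt(within * 0.5 * 0.5 + between * 0.15 * 0.85) / sqrt(60)
  # connectivity rejection slightly biases upward; allow 4 SE
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("censored walks emit distinct nodes consistent with the recorded walk", {
  truth <- generate_ground_truth(ground_truth_config(seed = 4))
  for (s in 1:10) {
    out <- simulate_fluency_list(truth, cohort_config(), participant_seed = s,
                                 return_walk = TRUE)
    expect_false(anyDuplicated(out$responses) > 0)
    # replay oracle: emitted = first occurrences of the walk, in order
    expect_identical(out$responses, unique(out$walk))
    # every non-jump transition follows an edge; with jump_prob = 0 all do
    out0 <- simulate_fluency_list(
      truth, cohort_config(jump_prob = 0), participant_seed = s,
      return_walk = TRUE)
    steps <- cbind(head(out0$walk, -1), out0$walk[-1])
    ids <- igraph::as_ids(igraph::V(truth))
    for (i in seq_len(nrow(steps))) {
      expect_true(igraph::are_adjacent(truth, steps[i, 1], steps[i, 2]))
    }
  }
})

test_that("a complete-graph truth yields uniform sampling without replacement", {
  truth <- generate_ground_truth(ground_truth_config(
    n_concepts = 15, n_modules = 1, p_in = 1, p_out = 0, seed = 5))
  out <- simulate_fluency_list(truth, cohort_config(list_length_mean = 8,
                                                    list_length_sd = 0),
                               participant_seed = 6)
  expect_length(out, 8)
  expect_false(anyDuplicated(out) > 0)
  one <- simulate_fluency_list(truth, cohort_config(list_length_mean = 1,
                                                    list_length_sd = 0),
                               participant_seed = 7)
  expect_length(one, 1)
})

test_that("cohort generation hits the target list lengths on average", {
  lens <- unlist(lapply(1:10, function(s) {
    coh <- suppressMessages(study_cohorts(seed = s))
    vapply(coh$records_a, function(r) length(r$responses), 0L)
  }))
  expect_lt(abs(mean(lens) - 16.4), 1.5)
})

test_that("cohort CSV export is byte-identical under a fixed master seed", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(suppressMessages(study_cohorts(seed = 21)), f1)
  write_cohort(suppressMessages(study_cohorts(seed = 21)), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".csv")
  write_cohort(suppressMessages(study_cohorts(seed = 22)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("exchangeable groups give pipeline t near zero on average", {
  truth <- generate_ground_truth(ground_truth_config(seed = 8))
  cfg <- cohort_config(n_participants = 25)
  ds <- vapply(1:4, function(s) {
    coh <- generate_cohort(truth, truth, cfg, cfg, labels = c("X", "Y"),
                           seed = s)
    ma <- build_response_matrix(coh$records_a)
    mb <- build_response_matrix(coh$records_b)
    b <- suppressMessages(casewise_bootstrap(ma, mb, iters = 20, seed = s,
                                             restarts = 3))
    mean(compare_bootstrap(b)$d)
  }, 0)
  expect_lt(abs(mean(ds)), 0.5)
})

test_that("raising between-module density lowers the estimated modularity", {
  qs <- sapply(1:6, function(s) {
    vapply(c(low = 0.02, high = 0.12), function(pout) {
      truth <- generate_ground_truth(ground_truth_config(p_out = pout,
                                                         seed = s))
      sal <- with_seed(s, exp(rnorm(120, 0, 1.3)))
      cfg <- cohort_config(n_participants = 36)
      coh <- generate_cohort(truth, truth, cfg, cfg, labels = c("X", "Y"),
                             seed = s, salience = sal)
      m <- suppressMessages(flunet:::estimate_pair(
        build_response_matrix(coh$records_a),
        build_response_matrix(coh$records_b), seed = s, restarts = 10))
      m$metrics_a$q
    }, 0)
  })
  expect_lt(median(qs["high", ]), median(qs["low", ]))
})
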