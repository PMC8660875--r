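# Case-wise bootstrap and distribution comparison.

make_cohort_mats <- function(seed = 1, n_a = 14, n_b = 12) {
  coh <- suppressMessages(
    study_cohorts(seed = seed))
  ma <- build_response_matrix(coh$records_a[seq_len(n_a)])
  mb <- build_response_matrix(coh$records_b[seq_len(n_b)])
  list(a = ma, b = mb)
}

test_that("bootstrap distributions have the right shape and provenance", {
  m <- make_cohort_mats(seed = 8, n_a = 20, n_b = 18)
  b <- suppressMessages(
    casewise_bootstrap(m$a, m$b, iters = 10, seed = 2, restarts = 3))
  for (g in c("a", "b")) {
    for (me in c("cc", "aspl", "q")) {
      d <- b[[g]][[me]]
      expect_s3_class(d, "metric_distribution")
      expect_length(as.numeric(d), 10)
      expect_true(all(is.finite(as.numeric(d))))
      expect_equal(attr(d, "provenance"), "bootstrap")
    }
  }
  expect_equal(b$iters, 10)
})

test_that("bootstrap is reproducible for a fixed seed", {
  m <- make_cohort_mats(seed = 9)
  b1 <- suppressMessages(casewise_bootstrap(m$a, m$b, iters = 6, seed = 3,
                                            restarts = 3))
  b2 <- suppressMessages(casewise_bootstrap(m$a, m$b, iters = 6, seed = 3,
                                            restarts = 3))
  expect_identical(lapply(b1$a, as.numeric), lapply(b2$a, as.numeric))
  expect_identical(lapply(b1$b, as.numeric), lapply(b2$b, as.numeric))
})

test_that("bootstrap distributions are invariant in law to participant order", {
  m <- make_cohort_mats(seed = 10)
  b1 <- suppressMessages(casewise_bootstrap(m$a, m$b, iters = 25, seed = 4,
                                            restarts = 3))
  perm <- response_matrix(unclass(m$a)[rev(seq_len(nrow(m$a))), ],
                          attr(m$a, "group"))
  b2 <- suppressMessages(casewise_bootstrap(perm, m$b, iters = 25, seed = 4,
                                            restarts = 3))
  # same law, so group means should be close (not identical: indices map
  # to different participants after permutation)
  expect_equal(mean(b1$a$cc), mean(b2$a$cc), tolerance = 0.05)
  expect_equal(mean(b1$a$q), mean(b2$a$q), tolerance = 0.2)
})

test_that("identical groups give small t statistics", {
  m <- make_cohort_mats(seed = 11, n_a = 20, n_b = 20)
  b <- suppressMessages(casewise_bootstrap(m$a, m$a, iters = 40, seed = 5,
                                           restarts = 3))
  cmp <- compare_bootstrap(b)
  expect_true(all(abs(cmp$d) < 0.5))
})

test_that("Student t, df and Cohen's d follow the pooled-variance formulas", {
  da <- metric_distribution("cc", c(1, 2, 3, 4, 5), seed = 1,
                            provenance = "bootstrap")
  db <- metric_distribution("cc", c(2, 4, 4, 5, 6), seed = 1,
                            provenance = "bootstrap")
  cmp <- compare_distributions(da, db)
  # longhand: means 3 and 4.2, pooled var = (4*2.5 + 4*2.2)/8 = 2.35
  sp <- sqrt(2.35)
  expect_equal(cmp$df, 8)
  expect_equal(cmp$t, (3 - 4.2) / (sp * sqrt(2 / 5)))
  expect_equal(cmp$d, (3 - 4.2) / sp)
  expect_equal(cmp$p, 2 * pt(-abs(cmp$t), 8))
  expect_equal(sign(cmp$t), sign(cmp$mean_a - cmp$mean_b))

  # shift-zero case
  cmp0 <- compare_distributions(da, da)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$d, 0)

  # 1000 vs 1000 draws give df = 1998
  d1 <- metric_distribution("q", rnorm(1000), seed = 1, provenance = "bootstrap")
  d2 <- metric_distribution("q", rnorm(1000), seed = 2, provenance = "bootstrap")
  expect_equal(compare_distributions(d1, d2)$df, 1998)

  expect_error(compare_distributions(da, db2 <- metric_distribution(
    "aspl", 1:5, seed = 1, provenance = "bootstrap")), "different")
})

test_that("bootstrap means approach the full-sample values as groups grow", {
  # consistency: the bootstrap-mean bias shrinks from a small to a large
  # cohort; uniform salience so the vocabulary saturates and resampling
  # noise is the only bias source
  truth <- generate_ground_truth(ground_truth_config(seed = 5))
  bias <- sapply(c(small = 60, large = 400), function(np) {
    cfg <- cohort_config(n_participants = np, seed = 5)
    coh <- generate_cohort(truth, truth, cfg, cfg, labels = c("X", "Y"),
                           seed = 5)
    ma <- build_response_matrix(coh$records_a)
    mb <- build_response_matrix(coh$records_b)
    eq <- equate_nodes(filter_min_occurrence(ma), filter_min_occurrence(mb))
    emp <- network_metrics(tmfg(cosine_association(eq$a)), seed = 1,
                           restarts = 20)
    b <- suppressMessages(casewise_bootstrap(ma, mb, iters = 20, seed = 6,
                                             restarts = 5))
    c(cc = abs(mean(b$a$cc) - emp$cc),
      aspl = abs(mean(b$a$aspl) - emp$aspl),
      q = abs(mean(b$a$q) - emp$q))
  })
  expect_lt(bias["aspl", "large"], bias["aspl", "small"])
  expect_lt(bias["cc", "large"], 0.02)
  expect_lt(bias["aspl", "large"], 0.3)
  expect_lt(bias["q", "large"], 0.03)
})

test_that("bootstrap CSV export is long-format with one row per iteration and group", {
  m <- make_cohort_mats(seed = 12)
  b <- suppressMessages(casewise_bootstrap(m$a, m$b, iters = 5, seed = 7,
                                           restarts = 3))
  f <- tempfile(fileext = ".csv")
  write_bootstrap(b, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 10)
  expect_named(df, c("group", "iteration", "cc", "aspl", "q"))
  expect_setequal(unique(df$group), c("A", "B"))
})

test_that("fixed-node-set bootstrap variant runs and keeps the node universe", {
  m <- make_cohort_mats(seed = 13, n_a = 20, n_b = 18)
  b <- suppressMessages(
    casewise_bootstrap(m$a, m$b, iters = 5, seed = 8, restarts = 3,
                       equate_per_iteration = FALSE))
  expect_length(as.numeric(b$a$cc), 5)
  expect_true(all(is.finite(as.numeric(b$a$cc))))
})
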