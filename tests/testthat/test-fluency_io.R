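# Reading, normalizing and tabulating fluency transcripts.

test_that("normalization removes repetitions, applies maps, drops off-category words", {
  lex <- normalization_rules(lexicon = c("cat", "dog"))
  r <- normalize_responses(rec("p1", "M", "cat", "cat", "dog"), lex)
  expect_equal(r$responses, c("cat", "dog"))

  r <- normalize_responses(rec("p1", "M"), lex)
  expect_equal(r$responses, character())

  rules <- normalization_rules(c(cats = "cat"), lexicon = c("cat", "dog"))
  r <- suppressMessages(
    normalize_responses(rec("p1", "M", "Cats", "unicorn", "dog"), rules))
  expect_equal(r$responses, c("cat", "dog"))
})

test_that("normalization folds case and accents and keeps first-occurrence order", {
  r <- normalize_responses(rec("p1", "M", "Léopard", "  ZEBRE ", "leopard"))
  expect_equal(r$responses, c("leopard", "zebre"))
  # unknown words without a lexicon are kept, not dropped
  r <- normalize_responses(rec("p1", "M", "dog", "axolotl"))
  expect_equal(r$responses, c("dog", "axolotl"))
})

test_that("normalization is idempotent", {
  rules <- normalization_rules(c(cats = "cat", doggy = "dog"),
                               lexicon = c("cat", "dog", "fox"))
  for (resp in list(c("Cats", "fox", "doggy", "cat"), character(),
                    c("FOX", "fox", "unicorn"))) {
    r1 <- suppressMessages(normalize_responses(rec("p", "M", resp), rules))
    r2 <- suppressMessages(normalize_responses(r1, rules))
    expect_identical(r1$responses, r2$responses)
  }
})

test_that("malformed rules are rejected", {
  expect_error(normalization_rules(c(cats = "cat", cat = "chat")),
               "fixed points")
  expect_error(normalization_rules(c(cats = "cat"), lexicon = "cats"),
               "canonical")
})

test_that("response matrix construction matches the produced sets", {
  recs <- list(rec("P1", "M", "cat", "dog"), rec("P2", "M", "dog"))
  m <- build_response_matrix(recs)
  expect_equal(colnames(m), c("cat", "dog"))
  expect_equal(unclass(m), rbind(c(1L, 1L), c(0L, 1L)), ignore_attr = TRUE)

  one <- build_response_matrix(list(rec("P9", "T", "a", "b", "c")))
  expect_equal(dim(one), c(1L, 3L))
  expect_true(all(one == 1L))

  # row sums = per-participant distinct counts; total = sum of distincts
  coh <- tiny_cohort()
  m <- build_response_matrix(coh$a)
  counts <- vapply(coh$a, function(r) length(unique(r$responses)), 0L)
  expect_equal(unname(rowSums(m)), counts)
  expect_equal(sum(m), sum(counts))
})

test_that("mixed groups and duplicate ids are rejected", {
  expect_error(build_response_matrix(list(rec("p1", "M", "cat"),
                                          rec("p2", "T", "dog"))),
               "split groups")
  expect_error(build_response_matrix(list(rec("p1", "M", "cat"),
                                          rec("p1", "M", "dog"))),
               "duplicate")
})

test_that("descriptives implement distinct and exclusive counts as set algebra", {
  A <- rmat(list(c(1, 1, 1), c(1, 0, 0)), c("cat", "dog", "fox"), "M")
  B <- rmat(list(c(1, 1), c(0, 1)), c("cat", "dog"), "T")
  d <- fluency_descriptives(A, B)
  expect_equal(d$group_a$n_distinct, 3)
  expect_equal(d$group_b$n_distinct, 2)
  expect_equal(d$group_a$n_exclusive, 1)
  expect_equal(d$group_b$n_exclusive, 0)

  d <- fluency_descriptives(A, A)
  expect_equal(d$group_a$n_exclusive, 0)
  expect_equal(d$group_b$n_exclusive, 0)
})

test_that("descriptives agree with brute-force set operations on a seeded cohort", {
  coh <- suppressMessages(study_cohorts(seed = 3))
  ma <- build_response_matrix(coh$records_a)
  mb <- build_response_matrix(coh$records_b)
  d <- fluency_descriptives(ma, mb)
  set_a <- unique(unlist(lapply(coh$records_a, `[[`, "responses")))
  set_b <- unique(unlist(lapply(coh$records_b, `[[`, "responses")))
  expect_equal(d$group_a$n_distinct, length(set_a))
  expect_equal(d$group_b$n_distinct, length(set_b))
  expect_equal(d$group_a$n_exclusive, length(setdiff(set_a, set_b)))
  expect_equal(d$group_b$n_exclusive, length(setdiff(set_b, set_a)))
  lens <- vapply(coh$records_a, function(r) length(r$responses), 0L)
  expect_equal(d$group_a$mean_responses, mean(lens))
  expect_equal(d$group_a$sd_responses, sd(lens))
})

test_that("descriptives are invariant to participant and response order", {
  coh <- tiny_cohort()
  d1 <- fluency_descriptives(build_response_matrix(coh$a),
                             build_response_matrix(coh$b))
  shuf <- lapply(rev(coh$a), function(r) {
    fluency_record(r$participant_id, r$group, rev(r$responses))
  })
  d2 <- fluency_descriptives(build_response_matrix(shuf),
                             build_response_matrix(coh$b))
  expect_equal(d1, d2)
})

test_that("transcript and matrix CSV round-trips preserve content", {
  coh <- tiny_cohort()
  df <- do.call(rbind, lapply(c(coh$a, coh$b), function(r) {
    data.frame(participant_id = r$participant_id, group = r$group,
               rank = seq_along(r$responses), response = r$responses)
  }))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  recs <- read_fluency(f)
  expect_length(recs, 6)
  expect_equal(recs[[1]]$responses, c("cat", "dog", "fox"))

  m <- build_response_matrix(coh$a)
  f2 <- tempfile(fileext = ".csv")
  write_response_matrix(m, f2)
  back <- read.csv(f2, check.names = FALSE)
  expect_equal(back$participant_id, rownames(m))
  expect_equal(as.matrix(back[, -1]), unclass(m), ignore_attr = TRUE)
})

test_that("normalization rule files are read correctly", {
  vf <- tempfile(fileext = ".csv")
  writeLines(c("variant,canonical", "cats,cat", "Chien,chien"), vf)
  lf <- tempfile(fileext = ".txt")
  writeLines(c("cat", "chien", ""), lf)
  rules <- read_normalization(vf, lf)
  expect_equal(unname(rules$variant_map["cats"]), "cat")
  expect_equal(rules$lexicon, c("cat", "chien"))
})
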