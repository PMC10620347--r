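# build a pmi_table whose raw counts equal a given word x class matrix
table_from_counts <- function(counts, alpha) {
  docs <- list()
  labs <- character(0)
  for (cls in colnames(counts)) {
    toks <- rep(rownames(counts), counts[, cls])
    if (length(toks) > 0) {
      docs <- c(docs, list(toks))
      labs <- c(labs, cls)
    }
  }
  pmi_table(docs, labs, alpha = alpha)
}

test_that("PMI is zero under exact independence", {
  counts <- matrix(c(1, 1, 1, 1), 2, 2,
                   dimnames = list(c("x", "y"), c("A", "B")))
  tab <- table_from_counts(counts, alpha = 0)
  expect_equal(pmi("x", "A", tab), 0)
  expect_equal(pmi("y", "B", tab), 0)
})

test_that("the worked ratio example gives ln 2", {
  # n(x,A) = 4, n(x) = 4, n(A) = 5, N = 10
  counts <- matrix(c(4, 1, 0, 5), 2, 2,
                   dimnames = list(c("x", "z"), c("A", "B")))
  tab <- table_from_counts(counts, alpha = 0)
  expect_equal(pmi("x", "A", tab), log(2))
})

test_that("unseen words error when smoothing is off", {
  counts <- matrix(c(2, 1), 2, 1, dimnames = list(c("x", "y"), "A"))
  counts <- cbind(counts, B = c(1, 2))
  tab0 <- table_from_counts(counts, alpha = 0)
  expect_error(pmi("nope", "A", tab0), "unseen")
  tab5 <- table_from_counts(counts, alpha = 0.5)
  expect_true(is.finite(pmi("nope", "A", tab5)))
  expect_error(pmi("x", "C", tab5), "unknown class")
})

test_that("PMI equals direct arithmetic on 100 random count tables", {
  set.seed(13)
  for (i in 1:100) {
    nw <- sample(3:8, 1)
    nc <- sample(2:3, 1)
    counts <- matrix(sample(0:6, nw * nc, TRUE), nw, nc,
                     dimnames = list(paste0("w", 1:nw),
                                     paste0("c", 1:nc)))
    counts[1, ] <- counts[1, ] + 1   # every class non-empty
    counts[, 1] <- counts[, 1] + 1   # every word observed at least once
    tab <- table_from_counts(counts, alpha = 0.5)
    w <- sample(rownames(counts), 1)
    cls <- sample(colnames(counts), 1)
    expect_lt(abs(pmi(w, cls, tab) - oracle_pmi(counts, w, cls, 0.5)),
              1e-12)
  }
})

test_that("PMI increases strictly in the joint count at fixed marginals", {
  base <- matrix(c(2, 4, 3, 1), 2, 2,
                 dimnames = list(c("x", "y"), c("A", "B")))
  shifted <- matrix(c(3, 3, 2, 2), 2, 2,
                    dimnames = list(c("x", "y"), c("A", "B")))
  # same row and column sums, n(x, A) raised by one
  expect_equal(rowSums(base), rowSums(shifted))
  expect_equal(colSums(base), colSums(shifted))
  t1 <- table_from_counts(base, 0.5)
  t2 <- table_from_counts(shifted, 0.5)
  expect_gt(pmi("x", "A", t2), pmi("x", "A", t1))
})

test_that("likely word sets contain class-exclusive words", {
  docs <- list(c("music", "walk"), c("music", "home"), c("go", "music"),
               c("praise", "walk"), c("praise", "home"), c("go", "praise"))
  labs <- c("ENV", "ENV", "ENV", "SELF", "SELF", "SELF")
  sets <- build_likely_word_sets(docs, labs, k = 2, min_count = 2)
  expect_true("music" %in% sets$ENV)
  expect_true("praise" %in% sets$SELF)
  expect_false("music" %in% sets$SELF)

  empty <- build_likely_word_sets(docs, labs, k = 0)
  expect_true(all(lengths(empty) == 0))
  expect_error(build_likely_word_sets(docs, labs, classes = c("ENV", "PREF")),
               "PREF")
})

test_that("statistically identical classes still build sets without error", {
  co <- generate_corpus(corpus_spec(
    class_counts = c(ENV = 30, SELF = 30, PREF = 30, COMP = 30,
                     NONSTRAT = 30),
    discriminability = 0, refusal_prob = 0, seed = 8))
  toks <- preprocess_corpus(co)
  sets <- build_likely_word_sets(toks, co$label, k = 10)
  expect_equal(length(sets), 5L)
  expect_true(all(lengths(sets) <= 10))
})

test_that("likely-set features count set membership per class", {
  lex <- structure(list(A = c("music", "song"), B = c("song", "walk")),
                   class = "pmi_lexicon", k = 2)
  expect_equal(unname(likely_set_features(c("go", "home"), lex)), c(0, 0))
  # a token in two sets increments both
  expect_equal(unname(likely_set_features("song", lex)), c(1, 1))
  expect_equal(unname(likely_set_features(c("music", "song", "walk",
                                            "music"), lex)),
               c(3, 2))
  expect_equal(unname(likely_set_features(c("music", "music"), lex,
                                          type = "indicator")),
               c(1, 0))
})
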