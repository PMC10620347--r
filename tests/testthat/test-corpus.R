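test_that("default specification reproduces the published aggregates", {
  sp <- corpus_spec()
  expect_equal(unname(sp$class_counts["ENV"]), 975)
  expect_equal(sum(sp$class_counts), 1576)
  expect_equal(unname(sp$mean_lengths["NONSTRAT"]), 5.21)
  expect_equal(unname(sp$mean_lengths),
               c(7.20, 6.60, 7.64, 5.85, 5.21))
  expect_identical(corpus_spec(), corpus_spec())
})

test_that("spec validation rejects bad probabilities and counts", {
  expect_error(corpus_spec(discriminability = 1.2), "probabilities")
  expect_error(corpus_spec(refusal_prob = -0.1), "probabilities")
  expect_error(corpus_spec(class_counts = c(ENV = -1, SELF = 1, PREF = 1,
                                            COMP = 1, NONSTRAT = 1)),
               "non-negative")
})

test_that("generated per-class counts equal the spec exactly", {
  sp <- corpus_spec(class_counts = c(ENV = 3, SELF = 0, PREF = 0,
                                     COMP = 0, NONSTRAT = 2), seed = 1)
  co <- generate_corpus(sp)
  expect_equal(nrow(co), 5L)
  expect_equal(sum(co$label == "ENV"), 3L)
  expect_equal(sum(co$label == "NONSTRAT"), 2L)

  set.seed(99)
  for (i in 1:5) {
    counts <- setNames(sample(0:25, 5L), strategy_classes())
    co_i <- generate_corpus(corpus_spec(
      class_counts = counts,
      mean_lengths = c(ENV = 5, SELF = 5, PREF = 5, COMP = 5,
                       NONSTRAT = 5),
      seed = i))
    got <- table(factor(co_i$label, levels = strategy_classes()))
    expect_equal(as.integer(got), unname(as.integer(counts)))
    expect_false(anyDuplicated(co_i$id) > 0)
  }
})

test_that("the same seed reproduces the corpus byte for byte", {
  sp <- corpus_spec(class_counts = c(ENV = 10, SELF = 5, PREF = 5,
                                     COMP = 5, NONSTRAT = 5), seed = 7)
  expect_identical(generate_corpus(sp), generate_corpus(sp))
  for (seeds in list(c(1, 2), c(3, 4), c(10, 20))) {
    a <- generate_corpus(corpus_spec(class_counts = sp$class_counts,
                                     seed = seeds[1]))
    b <- generate_corpus(corpus_spec(class_counts = sp$class_counts,
                                     seed = seeds[2]))
    expect_true(any(a$text != b$text))
  }
})

test_that("realized class mean lengths track the spec at default sizes", {
  co <- generate_corpus(corpus_spec(seed = 11))
  expect_equal(nrow(co), 1576L)
  st <- corpus_stats(co)
  sp <- corpus_spec()
  for (cls in strategy_classes()) {
    expect_lt(abs(st$mean_length_per_class[[cls]] -
                    sp$mean_lengths[[cls]]), 0.5)
  }
})

test_that("zero discriminability never draws from the keyword pools", {
  sp <- corpus_spec(class_counts = c(ENV = 40, SELF = 40, PREF = 40,
                                     COMP = 40, NONSTRAT = 40),
                    discriminability = 0,
                    noise_rates = list(misspell_prob = 0, name_prob = 0,
                                       number_prob = 0, punct_prob = 0,
                                       stopword_prob = 0),
                    refusal_prob = 0, seed = 5)
  co <- generate_corpus(sp)
  toks <- tolower(unlist(strsplit(co$text, " ")))
  shared <- stratclass:::shared_vocabulary(sp$shared_vocab_size)
  expect_true(all(toks %in% shared))
})

test_that("corpus statistics match hand enumeration", {
  toy <- structure(data.frame(id = c("a", "b"),
                              text = c("a b", "b c"),
                              label = c("ENV", "SELF"),
                              stringsAsFactors = FALSE),
                   class = c("strategy_corpus", "data.frame"))
  st <- corpus_stats(toy)
  expect_equal(st$n_documents, 2L)
  expect_equal(st$n_tokens, 4L)
  expect_equal(st$vocab_size, 3L)
  expect_equal(st$mean_length_overall, 2.0)

  one <- structure(data.frame(id = "x", text = "x", label = "ENV",
                              stringsAsFactors = FALSE),
                   class = c("strategy_corpus", "data.frame"))
  st1 <- corpus_stats(one)
  expect_equal(st1$vocab_size, 1L)
  expect_equal(st1$mean_length_overall, 1.0)

  # 10-record toy with known token inventory, counted by hand
  texts <- c("go home now", "stay home", "go go go", "rest", "walk out",
             "sit down here", "sit", "home rest", "walk walk", "down")
  toy10 <- structure(data.frame(id = as.character(1:10), text = texts,
                                label = rep(c("ENV", "SELF"), 5L),
                                stringsAsFactors = FALSE),
                     class = c("strategy_corpus", "data.frame"))
  st10 <- corpus_stats(toy10)
  expect_equal(st10$n_tokens, 20L)
  expect_equal(st10$vocab_size, 10L)  # go home now stay rest walk out sit down here
  expect_equal(st10$mean_length_overall, 2.0)
  expect_equal(unname(st10$mean_length_per_class["ENV"]),
               mean(c(3, 3, 2, 1, 2)))

  expect_error(corpus_stats(toy[0, ]), "empty")
})

test_that("corpora round-trip through the TSV interchange format", {
  co <- small_corpus(seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(co, path)
  back <- read_corpus(path)
  expect_equal(back$id, co$id)
  expect_equal(back$text, co$text)
  expect_equal(back$label, co$label)
  header <- readLines(path, n = 1L)
  expect_identical(header, "id\ttext\tlabel")
})
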