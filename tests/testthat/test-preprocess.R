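test_that("edit distance agrees with the exhaustive recursive oracle", {
  expect_equal(edit_distance("play", "play"), 0L)
  expect_equal(edit_distance("", "abc"), 3L)
  expect_equal(edit_distance("kitten", "sitting"),
               oracle_edit_distance("kitten", "sitting"))
  expect_equal(edit_distance("kitten", "sitting"), 3L)

  set.seed(42)
  alphabet <- c("a", "b", "c", "d")
  for (i in 1:50) {
    a <- paste0(sample(alphabet, sample(0:6, 1), TRUE), collapse = "")
    b <- paste0(sample(alphabet, sample(0:6, 1), TRUE), collapse = "")
    expect_equal(edit_distance(a, b), oracle_edit_distance(a, b))
  }
})

test_that("edit distance is a metric on sampled triples", {
  set.seed(7)
  alphabet <- letters[1:5]
  rand_str <- function() paste0(sample(alphabet, sample(0:7, 1), TRUE),
                                collapse = "")
  for (i in 1:200) {
    a <- rand_str(); b <- rand_str(); c <- rand_str()
    expect_equal(edit_distance(a, a), 0L)
    expect_equal(edit_distance(a, b), edit_distance(b, a))
    expect_lte(edit_distance(a, c),
               edit_distance(a, b) + edit_distance(b, c))
    expect_equal(edit_distance(a, b) == 0L, a == b)
  }
})

test_that("spelling correction follows the distance-and-tie-break contract", {
  cfg <- preprocess_config(dictionary = c("music", "must", "bat", "cat"),
                           names = character(0))
  expect_equal(correct_spelling("music", cfg), "music")
  expect_equal(correct_spelling("mussic", cfg), "music")
  expect_equal(correct_spelling("zzzzzz", cfg), "zzzzzz")
  # distance ties: corpus frequency first, then lexicographic
  expect_equal(correct_spelling("aat", cfg), "bat")
  expect_equal(correct_spelling("aat", cfg, freq = c(cat = 5)), "cat")
  # placeholders and digit-bearing tokens are exempt
  expect_equal(correct_spelling(c("[name]", "7pm"), cfg),
               c("[name]", "7pm"))
})

test_that("entity replacement inserts the documented placeholders", {
  expect_equal(replace_entities("Anna sings daily"),
               "[name] sings daily")
  expect_equal(replace_entities("wake at 7"), "wake at [number]")
  expect_equal(replace_entities("sing a song"), "sing a song")
  # attached punctuation survives until the punctuation-removal step
  expect_equal(replace_entities("Anna!"), "[name]!")
})

test_that("lemmatization handles irregulars, suffixes and placeholders", {
  expect_equal(lemmatize("sung"), "sing")
  expect_equal(lemmatize("sing"), "sing")
  expect_equal(lemmatize("helping"), "help")
  expect_equal(lemmatize(c("running", "making", "babies", "boxes",
                           "needed", "tried", "games")),
               c("run", "make", "baby", "box", "need", "try", "game"))
  expect_equal(lemmatize("[name]"), "[name]")
  expect_equal(lemmatize("children"), "child")
})

test_that("the full pipeline applies the six steps in order", {
  out <- preprocess_text("Anna LOVES her drum!")
  expect_identical(out[[1]], c("[name]", "love", "drum"))
  expect_identical(preprocess_text("none")[[1]], "none")
  # pure-noise records come out empty and flagged, not as an error
  noise <- preprocess_text("the !!! of")
  expect_identical(noise[[1]], character(0))
  expect_true(attr(noise, "empty")[1])
})

test_that("pipeline output contains no uppercase, stopwords or punctuation", {
  co <- small_corpus(seed = 2)
  toks <- unlist(preprocess_corpus(co))
  expect_false(any(grepl("[A-Z]", toks)))
  expect_false(any(toks %in% default_stopwords()))
  expect_false(any(grepl("^[[:punct:]]+$", toks)))
  # placeholders survive punctuation removal intact
  expect_true(all(grepl("^[a-z0-9]+$|^\\[name\\]$|^\\[number\\]$", toks)))
})

test_that("the pipeline is idempotent on its own detokenized output", {
  co <- small_corpus(seed = 4)
  cores <- unique(unlist(strsplit(tolower(co$text), "[[:space:]]+")))
  cores <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", cores)
  cfg <- preprocess_config(
    dictionary = default_dictionary(cores[nzchar(cores) &
                                            !grepl("[0-9]", cores)]))
  p1 <- preprocess_text(co$text, cfg)
  keep <- lengths(p1) > 0
  detok <- vapply(p1[keep], paste, character(1), collapse = " ")
  p2 <- preprocess_text(detok, cfg)
  expect_identical(unname(p2[seq_along(p2)]), unname(p1[keep]))
})

test_that("the bundled stopword list has the documented size", {
  sw <- default_stopwords()
  expect_equal(length(sw), 127L)
  expect_false(anyDuplicated(sw) > 0)
  expect_false("none" %in% sw)
})
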