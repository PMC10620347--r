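oracle_stages_from_tokens <- function() {
  # stage oracles that read the gold label planted as the first token
  list(function(t) if (t[1] == "NONSTRAT") "NONSTRAT" else "STRATEGY",
       function(t) if (t[1] == "ENV") "EXTRINSIC" else "INTRINSIC",
       function(t) t[1])
}

test_that("the cascade composes stage decisions into five classes", {
  labs <- c("ENV", "SELF", "PREF", "COMP", "NONSTRAT")
  toks <- lapply(labs, function(l) c(l, "filler"))
  got <- cascade_predict_corpus(toks, oracle_stages_from_tokens())
  expect_equal(got, labs)

  # oracle stages reproduce gold labels on a whole generated corpus
  co <- small_corpus(seed = 16)
  toks2 <- lapply(co$label, function(l) c(l, "pad"))
  expect_equal(cascade_predict_corpus(toks2, oracle_stages_from_tokens()),
               co$label)
})

test_that("later stages are never invoked after a stop", {
  calls <- new.env()
  calls$s2 <- 0L; calls$s3 <- 0L
  stages <- list(function(t) "NONSTRAT",
                 function(t) { calls$s2 <- calls$s2 + 1L; "EXTRINSIC" },
                 function(t) { calls$s3 <- calls$s3 + 1L; "SELF" })
  expect_equal(cascade_predict("whatever", stages), "NONSTRAT")
  expect_equal(calls$s2, 0L)
  expect_equal(calls$s3, 0L)

  stages[[1]] <- function(t) "STRATEGY"
  expect_equal(cascade_predict("whatever", stages), "ENV")
  expect_equal(calls$s3, 0L)
  expect_error(cascade_predict("x", list(function(t) "STRATEGY", NULL,
                                         NULL)),
               "stage")
})

test_that("majority-baseline stages label every record ENV", {
  labs <- study_labels()
  s1 <- fit_majority(task_labels(labs, 1))
  s2 <- fit_majority(task_labels(labs, 2)[task_labels(labs, 2) !=
                                            "EXCLUDED"])
  s3 <- fit_majority(task_labels(labs, 3)[task_labels(labs, 3) !=
                                            "EXCLUDED"])
  stages <- list(function(t) predict(s1, 1),
                 function(t) predict(s2, 1),
                 function(t) predict(s3, 1))
  got <- cascade_predict_corpus(list(c("a"), c("b"), c("c")), stages)
  expect_equal(got, rep("ENV", 3))
})

test_that("a stage-3 model must return an intrinsic class", {
  stages <- list(function(t) "STRATEGY", function(t) "INTRINSIC",
                 function(t) "ENV")
  expect_error(cascade_predict("x", stages), "non-intrinsic")
})

test_that("experiments are reproducible and respect the task domain", {
  co <- small_corpus(seed = 17)
  toks <- preprocess_corpus(co)
  cand <- list(features = feature_config("tfidf", max_terms = 300),
               model = model_config("svm"))
  e1 <- run_experiment(co, 3, cand, split_seed = 5, cv_seed = 5,
                       token_seqs = toks)
  e2 <- run_experiment(co, 3, cand, split_seed = 5, cv_seed = 5,
                       token_seqs = toks)
  expect_identical(e1$report, e2$report)
  expect_equal(e1$provenance$n_test,
               sum(largest_remainder_counts(table(
                 co$label[co$label %in% intrinsic_classes()]))))

  only_env <- co[co$label %in% c("ENV", "NONSTRAT"), ]
  class(only_env) <- c("strategy_corpus", "data.frame")
  expect_error(run_experiment(only_env, 3, cand), "task domain")
})

test_that("a learned experiment beats its majority counterpart", {
  co <- small_corpus(seed = 18, counts = c(ENV = 50, SELF = 25, PREF = 15,
                                           COMP = 15, NONSTRAT = 15))
  toks <- preprocess_corpus(co)
  svm <- run_experiment(co, 1,
                        list(features = feature_config("tfidf",
                                                       max_terms = 400),
                             model = model_config("svm")),
                        token_seqs = toks)
  base <- run_experiment(co, 1,
                         list(features = feature_config("tfidf",
                                                        max_terms = 400),
                              model = model_config("majority")),
                         token_seqs = toks)
  expect_gt(svm$report$accuracy, base$report$accuracy)
})

test_that("ablation reports one row per toggled block", {
  co <- small_corpus(seed = 19)
  toks <- preprocess_corpus(co)
  fc <- feature_config("tfidf", concepts = TRUE, max_terms = 300)
  ab <- run_ablation(co, 1, fc, model_config("svm"), token_seqs = toks)
  expect_equal(nrow(ab), 5L)
  expect_equal(ab$configuration,
               c("full", "-concepts", "-pos", "-dep", "-pmi"))
  expect_true(ab$applicable[2])
  expect_true(all(!ab$applicable[3:5]))
  expect_true(all(is.na(ab$accuracy[3:5])))
  expect_false(is.na(ab$accuracy[2]))
})

test_that("a YAML pipeline configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("features:", "  base: tfidf", "  pos: yes", "  k: 10",
               "model:", "  family: logistic", "  lambda: 0.5",
               "task: 2"), path)
  cfg <- read_pipeline_config(path)
  expect_s3_class(cfg$features, "feature_config")
  expect_true(cfg$features$pos)
  expect_equal(cfg$features$k, 10)
  expect_equal(cfg$model$family, "logistic")
  expect_equal(cfg$model$lambda, 0.5)
  expect_equal(cfg$task, 2)
})
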