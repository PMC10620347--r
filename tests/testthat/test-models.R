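test_that("the majority baseline stores the modal label with tie-break", {
  m <- fit_majority(c("A", "A", "B"))
  expect_equal(predict(m, 4), rep("A", 4))
  expect_equal(fit_majority(c("B", "A"))$stored_label, "A")
  expect_error(fit_majority(character(0)), "no training labels")
})

test_that("naive Bayes posteriors match the hand-enumerated toy", {
  docs <- list(c("fun", "fun"), c("fun", "good"), c("bad", "bad"))
  labs <- c("A", "A", "B")
  m <- fit_naive_bayes(docs, labs)
  # hand enumeration: |V| = 3; P(fun|A) = (3+1)/(4+3), P(fun|B) = (0+1)/(2+3)
  expect_equal(unname(nb_log_posterior(m, "fun")["A"]),
               log(2 / 3) + log(4 / 7))
  expect_equal(unname(nb_log_posterior(m, "fun")["B"]),
               log(1 / 3) + log(1 / 5))
  expect_equal(predict(m, list("fun")), "A")
  # unknown words are removed: an all-unknown document falls back to priors
  expect_equal(predict(m, list(c("zzz", "qqq"))), "A")
  expect_equal(nb_log_posterior(m, c("zzz")), m$log_prior)
  expect_error(fit_naive_bayes(docs, c("A", "A", "A")), "two classes")
})

test_that("per-class token likelihoods normalize over the vocabulary", {
  co <- small_corpus(seed = 9)
  toks <- preprocess_corpus(co)
  m <- fit_naive_bayes(toks, co$label)
  for (cls in m$classes) {
    expect_lt(abs(sum(exp(m$log_likelihood[, cls])) - 1), 1e-9)
  }
})

test_that("naive Bayes agrees with brute force on 50 random tiny corpora", {
  set.seed(21)
  vocab <- c("w1", "w2", "w3", "w4")
  for (i in 1:50) {
    k <- sample(2:3, 1)
    classes <- LETTERS[1:k]
    docs <- list(); labs <- character(0)
    for (cls in classes) {
      for (d in seq_len(sample(2:4, 1))) {
        docs <- c(docs, list(sample(vocab, sample(1:4, 1), TRUE)))
        labs <- c(labs, cls)
      }
    }
    m <- fit_naive_bayes(docs, labs)
    test_doc <- sample(c(vocab, "unseen"), sample(1:4, 1), TRUE)
    got <- nb_log_posterior(m, test_doc)
    want <- oracle_nb_scores(docs, labs, test_doc)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
    expect_equal(predict(m, list(test_doc)),
                 names(want)[which.max(want)])
  }
})

test_that("logistic regression separates well-separated clusters", {
  set.seed(5)
  x <- rbind(matrix(rnorm(40, mean = -3, sd = 0.3), ncol = 2),
             matrix(rnorm(40, mean = 3, sd = 0.3), ncol = 2))
  y <- rep(c("A", "B"), each = 20)
  m <- fit_logistic(x, y, lambda = 0.01, seed = 2)
  expect_equal(mean(predict(m, x) == y), 1.0)
  p <- predict(m, x, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
})

test_that("symmetric data puts the logistic decision threshold at zero", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c("A", "B")
  m <- fit_logistic(x, y, lambda = 0, max_epochs = 100, seed = 3)
  # symmetry forces w > 0, b = 0: threshold at the origin
  expect_lt(abs(m$b[1] - (-m$b[2])), 1e-8)
  expect_equal(predict(m, matrix(c(-0.01, 0.01), ncol = 1)), c("A", "B"))
  p <- predict(m, matrix(0), type = "prob")
  expect_lt(abs(p[1, "A"] - 0.5), 1e-6)
})

test_that("the symmetric point pair yields the maximum-margin SVM", {
  x <- matrix(c(-1, 1), ncol = 1)
  y <- c("N", "P")
  m <- fit_linear_svm(x, y, C = 1000)
  w <- m$W[1, "P"]; b <- m$b["P"]
  # closed form: w = 1, b = 0, margin 2/|w| = 2
  expect_lt(abs(w - 1), 1e-3)
  expect_lt(abs(b), 1e-3)
  expect_equal(predict(m, matrix(c(-0.5, 0.5), ncol = 1)), c("N", "P"))
})

test_that("a separable toy is fit with zero training errors", {
  set.seed(11)
  x <- rbind(matrix(rnorm(30, -2, 0.2), ncol = 2),
             matrix(rnorm(30, 2, 0.2), ncol = 2),
             cbind(rnorm(15, -2, 0.2), rnorm(15, 2, 0.2)))
  y <- rep(c("A", "B", "C"), each = 15)
  m <- fit_linear_svm(x, y, C = 10)
  expect_equal(mean(predict(m, x) == y), 1.0)
  expect_equal(m$scheme, "one-vs-rest")
})

test_that("the SVM objective matches a dense grid search on 4 points", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  yraw <- c("N", "N", "P", "P")
  C <- 1
  m <- fit_linear_svm(x, yraw, C = C, tol = 1e-8)
  w <- m$W[1, "P"]; b <- unname(m$b["P"])
  obj <- function(w, b) {
    y <- c(-1, -1, 1, 1)
    0.5 * (w^2 + b^2) + C * sum(pmax(0, 1 - y * (w * x[, 1] + b)))
  }
  grid <- seq(-1.5, 1.5, by = 0.002)
  gb <- expand.grid(w = grid, b = grid)
  y <- c(-1, -1, 1, 1)
  vals <- 0.5 * (gb$w^2 + gb$b^2)
  for (i in 1:4) {
    vals <- vals + C * pmax(0, 1 - y[i] * (gb$w * x[i, 1] + gb$b))
  }
  expect_lte(obj(w, b), min(vals) + 1e-3)
})

test_that("the hand-rolled SVM agrees with an independent solver", {
  set.seed(17)
  x <- rbind(matrix(rnorm(60, -2, 0.4), ncol = 2),
             matrix(rnorm(60, 2, 0.4), ncol = 2))
  y <- rep(c("A", "B"), each = 30)
  m <- fit_linear_svm(x, y, C = 1)
  ref <- e1071::svm(x, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE)
  expect_equal(predict(m, x), as.character(predict(ref, x)))
})

test_that("model training is deterministic given seed and config", {
  co <- small_corpus(seed = 10)
  toks <- preprocess_corpus(co)
  fm <- fit_feature_models(toks, co$label, feature_config("tfidf",
                                                          max_terms = 100))
  X <- build_feature_matrix(toks, fm)
  l1 <- fit_logistic(X, co$label, seed = 4)
  l2 <- fit_logistic(X, co$label, seed = 4)
  expect_identical(l1$W, l2$W)
  s1 <- fit_linear_svm(X, co$label)
  s2 <- fit_linear_svm(X, co$label)
  expect_identical(s1$W, s2$W)
  expect_error(fit_logistic(matrix(c(1, NA), 2, 1), c("A", "B")),
               "finite")
  expect_error(fit_linear_svm(matrix(c(1, Inf), 2, 1), c("A", "B")),
               "finite")
})
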