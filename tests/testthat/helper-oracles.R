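# Independent oracles used across the suite. These deliberately do not
# share code with the package implementation.

# exhaustive recursion (keep strings short: exponential)
oracle_edit_distance <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  rest_a <- substr(a, 2L, nchar(a))
  rest_b <- substr(b, 2L, nchar(b))
  cost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  min(oracle_edit_distance(rest_a, b) + 1L,
      oracle_edit_distance(a, rest_b) + 1L,
      oracle_edit_distance(rest_a, rest_b) + cost)
}

# direct arithmetic on a word-by-class count matrix
oracle_pmi <- function(counts, w, cls, alpha) {
  N <- sum(counts)
  nW <- nrow(counts)
  nC <- ncol(counts)
  denom <- N + alpha * nW * nC
  p_wc <- (counts[w, cls] + alpha) / denom
  p_w <- (sum(counts[w, ]) + alpha * nC) / denom
  p_c <- (sum(counts[, cls]) + alpha * nW) / denom
  log(p_wc / (p_w * p_c))
}

# brute-force Laplace-smoothed naive Bayes log posterior
oracle_nb_scores <- function(train_docs, train_labels, test_tokens) {
  classes <- sort(unique(train_labels))
  vocab <- sort(unique(unlist(train_docs)))
  test_tokens <- test_tokens[test_tokens %in% vocab]
  vapply(classes, function(cls) {
    docs <- train_docs[train_labels == cls]
    toks <- unlist(docs)
    s <- log(sum(train_labels == cls) / length(train_labels))
    for (tk in test_tokens) {
      s <- s + log((sum(toks == tk) + 1) / (length(toks) + length(vocab)))
    }
    s
  }, numeric(1L))
}

# metrics from a gold x predicted confusion matrix, straight from the
# definitions
oracle_metrics <- function(conf) {
  classes <- rownames(conf)
  p <- r <- f <- numeric(length(classes))
  for (i in seq_along(classes)) {
    tp <- conf[i, i]
    p[i] <- if (sum(conf[, i]) == 0) 0 else tp / sum(conf[, i])
    r[i] <- if (sum(conf[i, ]) == 0) 0 else tp / sum(conf[i, ])
    f[i] <- if (p[i] + r[i] == 0) 0 else 2 * p[i] * r[i] / (p[i] + r[i])
  }
  list(accuracy = sum(diag(conf)) / sum(conf),
       macro_precision = mean(p), macro_recall = mean(r),
       macro_f1 = mean(f), f1 = f)
}

# expand a gold x predicted confusion matrix into label vectors
labels_from_confusion <- function(conf) {
  gold <- pred <- character(0L)
  for (i in rownames(conf)) {
    for (j in colnames(conf)) {
      k <- conf[i, j]
      gold <- c(gold, rep(i, k))
      pred <- c(pred, rep(j, k))
    }
  }
  list(gold = gold, pred = pred)
}

# the published per-class record counts
study_class_counts <- function() {
  c(ENV = 975, SELF = 307, PREF = 84, COMP = 104, NONSTRAT = 106)
}

study_labels <- function() {
  rep(names(study_class_counts()), times = study_class_counts())
}

# small, quickly generated corpus for pipeline tests
small_corpus <- function(seed = 1, counts = c(ENV = 40, SELF = 20,
                                              PREF = 12, COMP = 12,
                                              NONSTRAT = 14),
                         discriminability = 0.9) {
  generate_corpus(corpus_spec(
    class_counts = counts,
    mean_lengths = c(ENV = 7.2, SELF = 6.6, PREF = 7.6, COMP = 5.8,
                     NONSTRAT = 5.2),
    discriminability = discriminability, seed = seed))
}
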