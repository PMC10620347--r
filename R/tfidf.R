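# TF-IDF document representation. Dialect (recorded in the model object):
# vocabulary = the max_terms most frequent training terms (ties broken
# lexicographically), idf(t) = ln((1 + N) / (1 + df(t))) + 1, weight = raw
# term frequency times idf, vectors L2-normalized, out-of-vocabulary
# tokens ignored.

#' Fit a TF-IDF model on training token sequences
#'
#' @param token_seqs List of training token vectors.
#' @param max_terms Vocabulary cap; the `max_terms` most frequent terms
#'   are kept (frequency ties broken lexicographically). Default 5000.
#' @return An object of class `tfidf_model` with elements `vocabulary`,
#'   `document_frequency`, `idf`, `n_train_docs` and `dialect`.
#' @export
#' @examples
#' m <- fit_tfidf(list(c("a", "b"), c("a", "c")))
#' m$idf[["a"]]  # ln(3/3) + 1 = 1
fit_tfidf <- function(token_seqs, max_terms = 5000) {
  if (length(token_seqs) == 0L) stop("training set is empty")
  tf_all <- table(unlist(token_seqs))
  if (length(tf_all) == 0L) stop("training set has no tokens")
  ord <- order(-as.numeric(tf_all), names(tf_all))
  vocab <- names(tf_all)[ord][seq_len(min(max_terms, length(tf_all)))]
  df <- vapply(vocab, function(t) {
    sum(vapply(token_seqs, function(d) t %in% d, logical(1L)))
  }, numeric(1L))
  n <- length(token_seqs)
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocabulary = vocab,
                 document_frequency = df,
                 idf = idf,
                 n_train_docs = n,
                 dialect = "tf_raw.idf_smooth_ln.l2norm"),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("TF-IDF model: %d terms over %d training documents (%s)\n",
              length(x$vocabulary), x$n_train_docs, x$dialect))
  invisible(x)
}

#' Transform token sequences into TF-IDF vectors
#'
#' @param object A `tfidf_model`.
#' @param newdata A list of token vectors (or a single character vector).
#' @param ... Unused.
#' @return Numeric matrix, one row per document, columns in vocabulary
#'   order; rows are L2-normalized (all-zero rows stay zero).
#' @export
predict.tfidf_model <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- list(newdata)
  vocab <- object$vocabulary
  out <- matrix(0, nrow = length(newdata), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(newdata)) {
    tk <- newdata[[i]]
    tk <- tk[tk %in% vocab]
    if (length(tk) == 0L) next
    tf <- table(tk)
    w <- as.numeric(tf) * object$idf[names(tf)]
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    out[i, names(tf)] <- w
  }
  out
}
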