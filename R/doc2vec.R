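# Paragraph-vector document embeddings, distributed-memory variant with
# negative sampling. Each document holds a trainable vector that is
# averaged with the window context word vectors to predict the center
# word; unseen documents are embedded by gradient inference against the
# frozen word matrices. Single-threaded and fully seeded, so training and
# inference are deterministic.

sigmoid_clip <- function(x) 1 / (1 + exp(-pmax(pmin(x, 6), -6)))

sample_negatives <- function(cum, k) {
  findInterval(runif(k), cum) + 1L
}

#' Fit paragraph-vector document embeddings
#'
#' Trains distributed-memory paragraph vectors with negative sampling over
#' exactly `epochs` passes of the training sequences. Deterministic given
#' `seed` (single worker, fixed document order, seeded sampling).
#'
#' @param token_seqs List of training token vectors.
#' @param dim Embedding dimensionality (default 100).
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary (default 1).
#' @param epochs Number of complete passes (default 30).
#' @param window Context window half-width (default 5).
#' @param negative Negative samples per position (default 5).
#' @param alpha,min_alpha Initial and final learning rate (linear decay
#'   across epochs).
#' @param seed Integer RNG seed.
#' @return An object of class `doc2vec_model` holding the word matrices,
#'   the trained document vectors and all hyperparameters.
#' @export
fit_doc2vec <- function(token_seqs, dim = 100, min_count = 1, epochs = 30,
                        window = 5, negative = 5, alpha = 0.025,
                        min_alpha = 1e-4, seed = 42) {
  if (length(token_seqs) == 0L) stop("training set is empty")
  counts <- table(unlist(token_seqs))
  vocab <- sort(names(counts)[counts >= min_count])
  if (length(vocab) == 0L) stop("no vocabulary at this min_count")
  vocab_index <- setNames(seq_along(vocab), vocab)
  # negative-sampling distribution: unigram^0.75
  p <- as.numeric(counts[vocab])^0.75
  cum <- cumsum(p / sum(p))
  n_docs <- length(token_seqs)
  env <- new.env()
  with_seed(seed, {
    env$W <- matrix(runif(length(vocab) * dim, -0.5, 0.5) / dim,
                    nrow = length(vocab))
    env$O <- matrix(0, nrow = length(vocab), ncol = dim)
    env$D <- matrix(runif(n_docs * dim, -0.5, 0.5) / dim, nrow = n_docs)
    for (ep in seq_len(epochs)) {
      lr <- alpha - (alpha - min_alpha) * (ep - 1) / max(epochs - 1, 1)
      local_train(env, seq_len(n_docs), token_seqs, vocab_index, dim,
                  window, negative, lr, cum, infer_only = FALSE)
    }
  })
  structure(list(vocabulary = vocab, vocab_index = vocab_index,
                 W = env$W, O = env$O, doc_vectors = env$D,
                 cum = cum, dim = dim, min_count = min_count,
                 epochs = epochs, window = window, negative = negative,
                 alpha = alpha, min_alpha = min_alpha, seed = seed),
            class = "doc2vec_model")
}

# in-place pass over all positions of all sequences
local_train <- function(env, doc_rows, seqs, vocab_index, dim, window,
                        negative, lr, cum, infer_only) {
  for (di in seq_along(seqs)) {
    ids <- unname(vocab_index[seqs[[di]]])
    ids <- ids[!is.na(ids)]
    L <- length(ids)
    if (L == 0L) next
    drow <- doc_rows[di]
    for (pos in seq_len(L)) {
      lo <- max(1L, pos - window)
      hi <- min(L, pos + window)
      ctx <- ids[setdiff(lo:hi, pos)]
      nctx <- length(ctx) + 1L
      h <- env$D[drow, ]
      if (length(ctx) == 1L) {
        h <- h + env$W[ctx, ]
      } else if (length(ctx) > 1L) {
        h <- h + colSums(env$W[ctx, , drop = FALSE])
      }
      h <- h / nctx
      negs <- sample_negatives(cum, negative)
      targets <- c(ids[pos], negs)
      err <- numeric(dim)
      for (j in seq_along(targets)) {
        t <- targets[j]
        if (j > 1L && t == ids[pos]) next
        f <- sigmoid_clip(sum(h * env$O[t, ]))
        g <- ((j == 1L) - f) * lr
        err <- err + g * env$O[t, ]
        if (!infer_only) env$O[t, ] <- env$O[t, ] + g * h
      }
      env$D[drow, ] <- env$D[drow, ] + err
      if (!infer_only) {
        for (cc in ctx) env$W[cc, ] <- env$W[cc, ] + err
      }
    }
  }
}

#' @export
print.doc2vec_model <- function(x, ...) {
  cat(sprintf(
    "Paragraph-vector model: dim %d, vocab %d, %d docs, %d epochs\n",
    x$dim, length(x$vocabulary), nrow(x$doc_vectors), x$epochs))
  invisible(x)
}

#' Infer the embedding of a new document
#'
#' Gradient inference of a fresh document vector against the frozen word
#' matrices, run for the model's number of epochs. Each document is
#' inferred under its own reseeded stream, so the result depends only on
#' the tokens, the model and `seed`.
#'
#' @param model A `doc2vec_model`.
#' @param tokens Character vector of tokens (a single document).
#' @param seed RNG seed for inference; defaults to the model seed.
#' @return Numeric vector of length `model$dim`.
#' @export
infer_vector <- function(model, tokens, seed = model$seed) {
  env <- new.env()
  env$W <- model$W
  env$O <- model$O
  with_seed(seed, {
    env$D <- matrix(runif(model$dim, -0.5, 0.5) / model$dim, nrow = 1L)
    for (ep in seq_len(model$epochs)) {
      lr <- model$alpha - (model$alpha - model$min_alpha) * (ep - 1) /
        max(model$epochs - 1, 1)
      local_train(env, 1L, list(tokens), model$vocab_index, model$dim,
                  model$window, model$negative, lr, model$cum,
                  infer_only = TRUE)
    }
  })
  env$D[1L, ]
}

#' Embed token sequences with a fitted paragraph-vector model
#'
#' @param object A `doc2vec_model`.
#' @param newdata List of token vectors (or one character vector).
#' @param seed RNG seed for inference.
#' @param ... Unused.
#' @return Numeric matrix, one row per document, `object$dim` columns.
#' @export
predict.doc2vec_model <- function(object, newdata, seed = object$seed,
                                  ...) {
  if (is.character(newdata)) newdata <- list(newdata)
  out <- matrix(0, nrow = length(newdata), ncol = object$dim)
  for (i in seq_along(newdata)) {
    out[i, ] <- infer_vector(object, newdata[[i]], seed = seed)
  }
  out
}
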