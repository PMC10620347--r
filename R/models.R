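# The four classifier families: majority baseline, multinomial naive
# Bayes with Laplace smoothing, softmax logistic regression trained by
# mini-batch SGD, and a primal linear SVM trained by dual coordinate
# descent. All argmax ties break to the lexicographically smallest label.

#' Majority-class baseline
#'
#' Stores the modal training label (ties to the lexicographically
#' smallest) and predicts it for every record.
#'
#' @param labels Character vector of training labels.
#' @return An object of class `majority_model`.
#' @export
#' @examples
#' m <- fit_majority(c("A", "A", "B"))
#' predict(m, 3)
fit_majority <- function(labels) {
  if (length(labels) == 0L) stop("no training labels")
  tab <- table(labels)
  win <- names(tab)[tab == max(tab)]
  structure(list(stored_label = sort(win)[1L],
                 class_counts = tab),
            class = "majority_model")
}

#' @export
print.majority_model <- function(x, ...) {
  cat("Majority baseline: always predicts", x$stored_label, "\n")
  invisible(x)
}

#' @export
#' @rdname fit_majority
#' @param object Fitted model.
#' @param newdata Number of predictions wanted, or anything with a length
#'   (a list of token sequences, a feature matrix, ...).
#' @param ... Unused.
predict.majority_model <- function(object, newdata, ...) {
  n <- if (is.numeric(newdata) && length(newdata) == 1L) newdata
       else if (is.matrix(newdata)) nrow(newdata)
       else length(newdata)
  rep(object$stored_label, n)
}

#' Multinomial naive Bayes over token counts
#'
#' Bag-of-words naive Bayes with add-one (Laplace) smoothing:
#' P(w|c) = (count(w,c) + 1) / (count(c) + |V|). At prediction time,
#' tokens outside the training vocabulary are removed; a document with no
#' known token falls back to the class priors.
#'
#' @param token_seqs List of training token vectors.
#' @param labels Training labels; at least two distinct classes.
#' @return An object of class `naive_bayes_model` with `log_prior` and
#'   the `log_likelihood` matrix (vocabulary x classes).
#' @export
fit_naive_bayes <- function(token_seqs, labels) {
  labels <- as.character(labels)
  stopifnot(length(token_seqs) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  vocab <- sort(unique(unlist(token_seqs)))
  counts <- matrix(0, nrow = length(vocab), ncol = length(classes),
                   dimnames = list(vocab, classes))
  toks <- unlist(token_seqs)
  labs <- rep(labels, lengths(token_seqs))
  tab <- table(factor(toks, levels = vocab), factor(labs, levels = classes))
  counts[] <- as.numeric(tab)
  class_tokens <- colSums(counts)
  log_lik <- log(sweep(counts + 1, 2L, class_tokens + length(vocab), "/"))
  log_prior <- log(as.numeric(table(factor(labels, levels = classes))) /
                     length(labels))
  structure(list(classes = classes, vocabulary = vocab,
                 log_prior = setNames(log_prior, classes),
                 log_likelihood = log_lik),
            class = "naive_bayes_model")
}

#' @export
print.naive_bayes_model <- function(x, ...) {
  cat(sprintf("Multinomial naive Bayes: %d classes, vocabulary %d\n",
              length(x$classes), length(x$vocabulary)))
  invisible(x)
}

#' Log-posterior scores of a naive Bayes model
#'
#' @param model A `naive_bayes_model`.
#' @param tokens Character vector of tokens (one document).
#' @return Named numeric vector of unnormalized log posteriors, one per
#'   class.
#' @export
nb_log_posterior <- function(model, tokens) {
  tokens <- tokens[tokens %in% model$vocabulary]
  scores <- model$log_prior
  if (length(tokens) > 0L) {
    tf <- table(tokens)
    scores <- scores + as.numeric(
      t(model$log_likelihood[names(tf), , drop = FALSE]) %*% as.numeric(tf))
  }
  scores
}

#' @export
#' @rdname fit_naive_bayes
#' @param object Fitted model.
#' @param newdata List of token vectors (or one character vector).
#' @param ... Unused.
predict.naive_bayes_model <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- list(newdata)
  vapply(newdata, function(tk) {
    s <- nb_log_posterior(object, tk)
    object$classes[argmax_first(s)]   # classes sorted: ties break low
  }, character(1L))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Softmax logistic regression trained by mini-batch SGD
#'
#' Minimizes the mean cross-entropy plus an L2 penalty
#' `lambda/(2n) * ||W||^2` (bias unpenalized) by mini-batch stochastic
#' gradient descent with learning rate `learning_rate / sqrt(t)` over at
#' most `max_epochs` passes, stopping early when the full-data loss
#' improves by less than `tol`. For two classes the softmax reduces to
#' the sigmoid formulation.
#'
#' @param x Numeric feature matrix (finite values).
#' @param y Character vector of labels; at least two classes.
#' @param lambda L2 strength (default 1).
#' @param max_epochs Maximum optimizer epochs (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate Base learning rate (default 0.1).
#' @param tol Early-stopping tolerance on the loss (default 1e-4).
#' @param seed RNG seed for the per-epoch shuffles.
#' @return An object of class `logistic_model` with weight matrix `W`
#'   (features x classes) and bias vector `b`.
#' @export
fit_logistic <- function(x, y, lambda = 1, max_epochs = 100,
                         batch_size = 32, learning_rate = 0.1,
                         tol = 1e-4, seed = 42) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  n <- nrow(x); d <- ncol(x); kc <- length(classes)
  ymat <- outer(y, classes, "==") * 1
  W <- matrix(0, d, kc, dimnames = list(colnames(x), classes))
  b <- setNames(numeric(kc), classes)
  loss_fun <- function(W, b) {
    p <- softmax_rows(sweep(x %*% W, 2L, b, "+"))
    -mean(log(pmax(rowSums(p * ymat), 1e-300))) +
      lambda / (2 * n) * sum(W^2)
  }
  prev <- loss_fun(W, b)
  t_step <- 0L
  with_seed(seed, {
    for (ep in seq_len(max_epochs)) {
      idx <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        bi <- idx[start:min(start + batch_size - 1L, n)]
        t_step <- t_step + 1L
        lr <- learning_rate / sqrt(t_step)
        xb <- x[bi, , drop = FALSE]
        p <- softmax_rows(sweep(xb %*% W, 2L, b, "+"))
        err <- p - ymat[bi, , drop = FALSE]
        gW <- crossprod(xb, err) / length(bi) + (lambda / n) * W
        gb <- colMeans(err)
        W <- W - lr * gW
        b <- b - lr * gb
      }
      cur <- loss_fun(W, b)
      if (prev - cur < tol && ep > 1L) break
      prev <- cur
    }
  })
  structure(list(classes = classes, W = W, b = b, lambda = lambda,
                 max_epochs = max_epochs, batch_size = batch_size,
                 learning_rate = learning_rate, tol = tol, seed = seed,
                 final_loss = prev),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf(
    "Logistic regression (SGD): %d classes, %d features, lambda %.3g\n",
    length(x$classes), nrow(x$W), x$lambda))
  invisible(x)
}

#' @export
coef.logistic_model <- function(object, ...) {
  rbind(bias = object$b, object$W)
}

#' @export
#' @rdname fit_logistic
#' @param object Fitted model.
#' @param newdata Feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
predict.logistic_model <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  p <- softmax_rows(sweep(newdata %*% object$W, 2L, object$b, "+"))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  object$classes[apply(p, 1L, argmax_first)]
}

# dual coordinate descent for the L1-loss linear SVM
# primal: min 1/2 (||w||^2 + b^2) + C sum hinge  (bias as augmented
# feature, hence regularized)
svm_binary_dcd <- function(x, y, C, max_epochs = 200, tol = 1e-4) {
  n <- nrow(x)
  xa <- cbind(x, 1)            # augmented bias column
  qii <- rowSums(xa^2)
  alpha <- numeric(n)
  w <- numeric(ncol(xa))
  for (ep in seq_len(max_epochs)) {
    max_viol <- 0
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * xa[i, ]) - 1
      pg <- g
      if (alpha[i] <= 0) pg <- min(g, 0)
      if (alpha[i] >= C) pg <- max(g, 0)
      if (abs(pg) > 1e-12) {
        max_viol <- max(max_viol, abs(pg))
        a_new <- min(max(alpha[i] - g / qii[i], 0), C)
        if (a_new != alpha[i]) {
          w <- w + (a_new - alpha[i]) * y[i] * xa[i, ]
          alpha[i] <- a_new
        }
      }
    }
    if (max_viol < tol) break
  }
  list(w = w[-length(w)], b = w[length(w)], alpha = alpha)
}

#' Linear support-vector machine
#'
#' Primal objective `1/2 ||w||^2 + C * sum(hinge)` with the bias handled
#' as an augmented (hence regularized) feature, solved exactly by dual
#' coordinate descent in cyclic order — fully deterministic. Multiclass
#' problems are trained one-vs-rest; prediction is the argmax decision
#' value with lexicographic tie-break.
#'
#' @param x Numeric feature matrix (finite values).
#' @param y Character vector of labels; at least two classes.
#' @param C Hinge-loss trade-off (default 1).
#' @param max_epochs Maximum coordinate-descent epochs (default 200).
#' @param tol Stopping tolerance on the projected gradient (default 1e-4).
#' @return An object of class `linear_svm_model` with weight matrix `W`
#'   (features x classes for one-vs-rest; one column for binary) and bias
#'   vector `b`.
#' @export
fit_linear_svm <- function(x, y, C = 1, max_epochs = 200, tol = 1e-4) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes")
  fits <- lapply(classes, function(cls) {
    svm_binary_dcd(x, ifelse(y == cls, 1, -1), C, max_epochs, tol)
  })
  W <- vapply(fits, `[[`, numeric(ncol(x)), "w")
  W <- matrix(W, ncol = length(classes),
              dimnames = list(colnames(x), classes))
  b <- setNames(vapply(fits, `[[`, numeric(1L), "b"), classes)
  structure(list(classes = classes, W = W, b = b, C = C,
                 scheme = if (length(classes) == 2L) "one-vs-rest (binary)"
                          else "one-vs-rest"),
            class = "linear_svm_model")
}

#' @export
print.linear_svm_model <- function(x, ...) {
  cat(sprintf("Linear SVM (%s): %d classes, %d features, C %.3g\n",
              x$scheme, length(x$classes), nrow(x$W), x$C))
  invisible(x)
}

#' @export
coef.linear_svm_model <- function(object, ...) {
  rbind(bias = object$b, object$W)
}

#' Decision values of a linear SVM
#'
#' @param model A `linear_svm_model`.
#' @param newdata Feature matrix.
#' @return Numeric matrix of per-class decision values.
#' @export
svm_decision <- function(model, newdata) {
  out <- sweep(as.matrix(newdata) %*% model$W, 2L, model$b, "+")
  colnames(out) <- model$classes
  out
}

#' @export
#' @rdname fit_linear_svm
#' @param object Fitted model.
#' @param newdata Feature matrix.
#' @param ... Unused.
predict.linear_svm_model <- function(object, newdata, ...) {
  dv <- svm_decision(object, newdata)
  object$classes[apply(dv, 1L, argmax_first)]
}
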