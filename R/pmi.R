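# Pointwise mutual information between words and classes, and the
# PMI-selected "likely word sets" feature block built from it.
#
# PMI(w, c) = ln p(w, c) / (p(w) p(c)) over additively smoothed
# token-level counts: p(w, c) = (n(w, c) + a) / (N + a |W| |C|) with the
# marginals taken from the smoothed joint, so they remain consistent.

#' Build a word-by-class count table
#'
#' Token-level co-occurrence counts n(w, c) from training token sequences
#' and their labels.
#'
#' @param token_seqs List of token vectors (training data only).
#' @param labels Character vector of class labels, one per sequence.
#' @param alpha Additive smoothing constant (default 0.5).
#' @return An object of class `pmi_table` with the count matrix `counts`
#'   (words x classes), marginals and `alpha`.
#' @export
pmi_table <- function(token_seqs, labels, alpha = 0.5) {
  stopifnot(length(token_seqs) == length(labels), alpha >= 0)
  toks <- unlist(token_seqs)
  labs <- rep(as.character(labels), lengths(token_seqs))
  if (length(toks) == 0L) stop("no tokens in training data")
  counts <- table(factor(toks), factor(labs))
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts,
                 word_count = rowSums(counts),
                 class_count = colSums(counts),
                 total = sum(counts),
                 alpha = alpha),
            class = "pmi_table")
}

#' Pointwise mutual information of a word and a class
#'
#' @param w Word (must appear in the table when `alpha = 0`).
#' @param c Class label present in the table.
#' @param table A [pmi_table()].
#' @return Natural-log PMI of the smoothed probabilities.
#' @export
#' @examples
#' tab <- pmi_table(list(c("fun", "fun"), "bad"), c("A", "B"), alpha = 0)
#' pmi("fun", "A", tab)
pmi <- function(w, c, table) {
  stopifnot(inherits(table, "pmi_table"))
  if (!c %in% colnames(table$counts)) stop("unknown class: ", c)
  a <- table$alpha
  known <- w %in% rownames(table$counts)
  if (!known && a == 0) {
    stop("undefined PMI: word '", w, "' unseen and alpha = 0")
  }
  nW <- nrow(table$counts)
  nC <- ncol(table$counts)
  denom <- table$total + a * nW * nC
  nwc <- if (known) table$counts[w, c] else 0
  nw <- if (known) table$word_count[[w]] else 0
  nc <- table$class_count[[c]]
  p_wc <- (nwc + a) / denom
  p_w <- (nw + a * nC) / denom
  p_c <- (nc + a * nW) / denom
  log(p_wc / (p_w * p_c))
}

#' Likely word sets: the k words most associated with each class
#'
#' For every class in `labels`, ranks training words with total count at
#' least `min_count` by PMI with that class and keeps the top `k`. Ties
#' are broken by higher word frequency, then lexicographically. Built from
#' training data only.
#'
#' @param token_seqs List of training token vectors.
#' @param labels Class label per sequence; every class named in `classes`
#'   must occur.
#' @param k Words kept per class (default 20).
#' @param min_count Minimum total word count for eligibility (default 2).
#' @param alpha PMI smoothing constant (default 0.5).
#' @param classes Classes to build sets for; defaults to the classes
#'   present in `labels`.
#' @return An object of class `pmi_lexicon`: a named list of character
#'   vectors, one per class.
#' @export
build_likely_word_sets <- function(token_seqs, labels, k = 20,
                                   min_count = 2, alpha = 0.5,
                                   classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(as.character(labels)))
  missing_cls <- setdiff(classes, unique(as.character(labels)))
  if (length(missing_cls) > 0L) {
    stop("class(es) absent from training data: ",
         paste(missing_cls, collapse = ", "))
  }
  tab <- pmi_table(token_seqs, labels, alpha = alpha)
  eligible <- rownames(tab$counts)[tab$word_count >= min_count]
  sets <- lapply(classes, function(cls) {
    if (k == 0L || length(eligible) == 0L) return(character(0L))
    scores <- vapply(eligible, pmi, numeric(1L), c = cls, table = tab)
    ord <- order(-scores, -tab$word_count[eligible], eligible)
    eligible[ord][seq_len(min(k, length(eligible)))]
  })
  structure(setNames(sets, classes), class = "pmi_lexicon", k = k)
}

#' @export
print.pmi_lexicon <- function(x, ...) {
  cat(sprintf("PMI likely word sets (k = %d)\n", attr(x, "k")))
  for (cls in names(x)) {
    cat(" ", cls, ":", paste(head(x[[cls]], 8L), collapse = " "),
        if (length(x[[cls]]) > 8L) "..." else "", "\n")
  }
  invisible(x)
}

#' Likely-word-set feature block
#'
#' One count per class: the number of tokens belonging to that class's
#' likely word set (a token in several sets increments each).
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param lexicon A [build_likely_word_sets()] result.
#' @param type `"count"` (default) or `"indicator"` (0/1 per class).
#' @return Named numeric vector, one entry per class in lexicon order.
#' @export
likely_set_features <- function(tokens, lexicon, type = c("count",
                                                          "indicator")) {
  type <- match.arg(type)
  out <- vapply(lexicon, function(set) sum(tokens %in% set), numeric(1L))
  if (type == "indicator") out <- as.numeric(out > 0)
  out
}
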