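# Feature-vector assembly: a base document representation (TF-IDF or
# paragraph vectors) concatenated with optional hand-crafted blocks in the
# fixed order [base | pos | dep | pmi | concept]. All referenced models
# are fitted on training data only.

#' Feature configuration
#'
#' Declares which representation and hand-crafted blocks make up the
#' feature vector, plus their hyperparameters.
#'
#' @param base `"tfidf"` or `"doc2vec"`.
#' @param pos,dep,pmi,concepts Logical switches for the part-of-speech,
#'   dependency, likely-word-set and concept-lexicon blocks.
#' @param max_terms TF-IDF vocabulary cap (default 5000).
#' @param k Likely-word-set size per class (default 20).
#' @param min_count_pmi Minimum word count for PMI eligibility (default 2).
#' @param alpha PMI smoothing constant (default 0.5).
#' @param pmi_type `"count"` or `"indicator"` encoding of the pmi block.
#' @param dim,epochs,window,min_count Paragraph-vector hyperparameters
#'   (defaults 100 / 30 / 5 / 1).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(base = c("tfidf", "doc2vec"), pos = FALSE,
                           dep = FALSE, pmi = FALSE, concepts = FALSE,
                           max_terms = 5000, k = 20, min_count_pmi = 2,
                           alpha = 0.5, pmi_type = "count", dim = 100,
                           epochs = 30, window = 5, min_count = 1) {
  base <- match.arg(base)
  structure(list(base = base, pos = pos, dep = dep, pmi = pmi,
                 concepts = concepts, max_terms = max_terms, k = k,
                 min_count_pmi = min_count_pmi, alpha = alpha,
                 pmi_type = pmi_type, dim = dim, epochs = epochs,
                 window = window, min_count = min_count),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  blocks <- c("base", c("pos", "dep", "pmi", "concepts")[
    unlist(x[c("pos", "dep", "pmi", "concepts")])])
  cat(sprintf("Feature config: base=%s, blocks [%s]\n", x$base,
              paste(blocks, collapse = " | ")))
  invisible(x)
}

#' Encode lexicon concepts with a base representation
#'
#' Fits the active base representation (TF-IDF or paragraph vectors) on
#' the tokenized concept names of the lexicon, so assigned concepts can be
#' embedded alongside the document representation.
#'
#' @param lexicon A `concept_lexicon`.
#' @param base `"tfidf"` or `"doc2vec"`.
#' @param config A [feature_config()] supplying hyperparameters.
#' @param seed RNG seed (paragraph vectors only).
#' @return An object of class `concept_encoder`.
#' @export
fit_concept_encoder <- function(lexicon, base = "tfidf",
                                config = feature_config(), seed = 42) {
  name_tokens <- whitespace_tokenize(tolower(lexicon$concept))
  model <- if (base == "tfidf") {
    fit_tfidf(name_tokens, max_terms = config$max_terms)
  } else {
    fit_doc2vec(name_tokens, dim = config$dim, min_count = 1,
                epochs = config$epochs, window = config$window,
                seed = seed)
  }
  structure(list(base = base, model = model), class = "concept_encoder")
}

#' Concept feature block
#'
#' Embeds a set of assigned concept names (deduplicated first) with the
#' fitted concept encoder; the empty set maps to the zero vector.
#'
#' @param concepts Character vector of concept names, e.g. from
#'   [assign_concepts()].
#' @param encoder A [fit_concept_encoder()] result.
#' @return Numeric vector of the encoder's output dimensionality.
#' @export
concept_features <- function(concepts, encoder) {
  stopifnot(inherits(encoder, "concept_encoder"))
  dim_out <- if (encoder$base == "tfidf") {
    length(encoder$model$vocabulary)
  } else {
    encoder$model$dim
  }
  concepts <- unique(concepts)
  if (length(concepts) == 0L) return(numeric(dim_out))
  toks <- unlist(whitespace_tokenize(tolower(concepts)))
  as.numeric(predict(encoder$model, list(toks)))
}

#' Fit every model a feature configuration requires
#'
#' Fits the base representation on the training token sequences and, when
#' enabled, the PMI likely word sets and the concept encoder. Pass only
#' training data: everything downstream scores unseen records against
#' these fitted objects.
#'
#' @param token_seqs List of training token vectors.
#' @param labels Training labels (required when `config$pmi` is on).
#' @param config A [feature_config()].
#' @param lexicon A `concept_lexicon` (used when `config$concepts` is on).
#' @param seed RNG seed for the paragraph-vector base.
#' @return An object of class `feature_models`.
#' @export
fit_feature_models <- function(token_seqs, labels = NULL,
                               config = feature_config(),
                               lexicon = default_concept_lexicon(),
                               seed = 42) {
  base_model <- if (config$base == "tfidf") {
    fit_tfidf(token_seqs, max_terms = config$max_terms)
  } else {
    fit_doc2vec(token_seqs, dim = config$dim,
                min_count = config$min_count, epochs = config$epochs,
                window = config$window, seed = seed)
  }
  pmi_sets <- NULL
  if (isTRUE(config$pmi)) {
    if (is.null(labels)) stop("pmi block needs training labels")
    pmi_sets <- build_likely_word_sets(token_seqs, labels, k = config$k,
                                       min_count = config$min_count_pmi,
                                       alpha = config$alpha)
  }
  concept_encoder <- NULL
  if (isTRUE(config$concepts)) {
    concept_encoder <- fit_concept_encoder(lexicon, base = config$base,
                                           config = config, seed = seed)
  }
  structure(list(config = config, base = base_model,
                 pmi_sets = pmi_sets, concept_encoder = concept_encoder,
                 lexicon = lexicon,
                 pos_tagger = default_pos_tagger,
                 dep_parser = default_dep_parser),
            class = "feature_models")
}

#' Build the feature vector of one record
#'
#' Concatenates the enabled blocks in the fixed order
#' \[base | pos | dep | pmi | concept\]. The layout (attribute `segments`,
#' a named length vector) is identical for every document under one
#' configuration.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param models A [fit_feature_models()] result.
#' @return Numeric vector with attribute `segments`.
#' @export
build_feature_vector <- function(tokens, models) {
  stopifnot(inherits(models, "feature_models"))
  config <- models$config
  base <- as.numeric(predict(models$base, list(tokens)))
  parts <- list(base = base)
  if (isTRUE(config$pos)) {
    parts$pos <- pos_features(tokens, models$pos_tagger)
  }
  if (isTRUE(config$dep)) {
    parts$dep <- dep_features(tokens, models$dep_parser)
  }
  if (isTRUE(config$pmi)) {
    if (is.null(models$pmi_sets)) stop("pmi block enabled but not fitted")
    parts$pmi <- likely_set_features(tokens, models$pmi_sets,
                                     type = config$pmi_type)
  }
  if (isTRUE(config$concepts)) {
    if (is.null(models$concept_encoder)) {
      stop("concept block enabled but not fitted")
    }
    parts$concept <- concept_features(
      assign_concepts(tokens, models$lexicon), models$concept_encoder)
  }
  out <- unlist(parts, use.names = FALSE)
  attr(out, "segments") <- vapply(parts, length, integer(1L))
  out
}

#' Build the feature matrix of a corpus
#'
#' @param token_seqs List of token vectors.
#' @param models A [fit_feature_models()] result.
#' @return Numeric matrix, one row per document, with attribute
#'   `segments`.
#' @export
build_feature_matrix <- function(token_seqs, models) {
  first <- build_feature_vector(token_seqs[[1L]], models)
  out <- matrix(0, nrow = length(token_seqs), ncol = length(first))
  out[1L, ] <- first
  if (length(token_seqs) > 1L) {
    for (i in 2L:length(token_seqs)) {
      out[i, ] <- build_feature_vector(token_seqs[[i]], models)
    }
  }
  attr(out, "segments") <- attr(first, "segments")
  out
}
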