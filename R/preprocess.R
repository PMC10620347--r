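# Deterministic text preprocessing: case normalization, edit-distance
# spelling correction, entity placeholders, punctuation removal, stopword
# removal, lemmatization — applied in that order.

#' Bundled preprocessing resources
#'
#' `default_stopwords()` returns the fixed 127-word English stopword list
#' shipped with the package; `default_dictionary()` the bundled spelling
#' dictionary (optionally extended with a corpus vocabulary);
#' `default_name_gazetteer()` the personal-name inventory shared with the
#' synthetic-corpus generator; `default_lemma_exceptions()` the irregular
#' form-to-lemma table.
#'
#' @param extra Additional valid words (e.g. the training-corpus
#'   vocabulary) merged into the dictionary.
#' @return Character vector (or named character vector for the lemma
#'   exceptions, names = inflected forms).
#' @export
default_stopwords <- function() {
  read_wordfile("stopwords.txt")
}

#' @rdname default_stopwords
#' @export
default_dictionary <- function(extra = character()) {
  sort(unique(c(read_wordfile("wordlist.txt"), tolower(extra))))
}

#' @rdname default_stopwords
#' @export
default_name_gazetteer <- function() {
  default_name_gazetteer_values()
}

#' @rdname default_stopwords
#' @export
default_lemma_exceptions <- function() {
  path <- system.file("extdata", "lemma_exceptions.tsv",
                      package = "stratclass", mustWork = TRUE)
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  setNames(tab[[2L]], tab[[1L]])
}

#' Preprocessing configuration
#'
#' @param max_edit_distance Maximum Levenshtein distance for spelling
#'   correction (default 2); candidates farther than this leave the token
#'   unchanged.
#' @param name_placeholder,number_placeholder Placeholder tokens inserted
#'   for recognized personal names and digit-bearing tokens.
#' @param stopwords Lowercase stopword list.
#' @param dictionary Lowercase valid-word list used by spelling correction
#'   and lemma validation.
#' @param names Personal-name gazetteer (lowercase) for entity replacement.
#' @param lemma_exceptions Named character vector mapping irregular forms
#'   to lemmas.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(max_edit_distance = 2,
                              name_placeholder = "[name]",
                              number_placeholder = "[number]",
                              stopwords = default_stopwords(),
                              dictionary = default_dictionary(),
                              names = default_name_gazetteer(),
                              lemma_exceptions = default_lemma_exceptions()) {
  stopifnot(max_edit_distance >= 0, nzchar(name_placeholder),
            nzchar(number_placeholder))
  structure(list(max_edit_distance = as.integer(max_edit_distance),
                 name_placeholder = name_placeholder,
                 number_placeholder = number_placeholder,
                 stopwords = stopwords,
                 dictionary = dictionary,
                 names = names,
                 lemma_exceptions = lemma_exceptions),
            class = "preprocess_config")
}

#' Levenshtein edit distance
#'
#' Minimum number of unit-cost insertions, deletions and substitutions
#' transforming one string into another. Vectorized over `a` and `b`
#' (recycled).
#'
#' @param a,b Character vectors.
#' @return Non-negative integer vector of distances.
#' @export
#' @examples
#' edit_distance("kitten", "sitting")  # 3
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n),
         function(i) as.integer(adist(a[i], b[i], costs = 1L)),
         integer(1L))
}

strip_affixes <- function(tok) {
  core <- gsub("^[[:punct:]]+", "", tok)
  core <- gsub("[[:punct:]]+$", "", core)
  core
}

#' Spelling correction by minimal edit distance
#'
#' Tokens already in the dictionary, placeholders, digit-bearing tokens and
#' gazetteer names pass through unchanged; any other token is replaced by
#' the dictionary word at minimal edit distance, provided that distance is
#' at most `max_edit_distance`. Ties are broken by higher corpus frequency
#' (when `freq` is supplied), then lexicographically.
#'
#' @param tokens Lowercase character vector.
#' @param config A [preprocess_config()].
#' @param freq Optional named numeric vector of dictionary-word
#'   frequencies used for tie-breaking.
#' @return Character vector of corrected tokens.
#' @export
correct_spelling <- function(tokens, config = preprocess_config(),
                             freq = NULL) {
  exempt <- is_placeholder(tokens) | grepl("[0-9]", tokens) |
    tokens %in% config$dictionary | tokens %in% config$names |
    !nzchar(tokens)
  todo <- unique(tokens[!exempt])
  if (length(todo) == 0L) return(tokens)
  d <- adist(todo, config$dictionary, costs = 1L)
  repl <- vapply(seq_along(todo), function(i) {
    row <- d[i, ]
    m <- min(row)
    if (m > config$max_edit_distance) return(todo[i])
    cand <- config$dictionary[row == m]
    if (length(cand) > 1L) {
      f <- if (is.null(freq)) numeric(length(cand)) else {
        out <- freq[cand]
        out[is.na(out)] <- 0
        out
      }
      cand <- cand[order(-f, cand)]
    }
    cand[1L]
  }, character(1L))
  map <- setNames(repl, todo)
  out <- tokens
  hit <- !exempt & tokens %in% todo
  out[hit] <- map[tokens[hit]]
  out
}

#' Replace personal names and numbers with placeholders
#'
#' Whitespace tokens whose alphabetic core matches the name gazetteer
#' (case-insensitively) become the name placeholder; tokens containing any
#' digit become the number placeholder; attached punctuation is preserved
#' for the later punctuation-removal step.
#'
#' @param text Character vector of raw texts.
#' @param config A [preprocess_config()].
#' @return Character vector of texts with placeholders substituted.
#' @export
#' @examples
#' replace_entities("Anna sings daily")  # "[name] sings daily"
replace_entities <- function(text, config = preprocess_config()) {
  vapply(text, function(tx) {
    toks <- strsplit(trimws(tx), "[[:space:]]+")[[1L]]
    out <- vapply(toks, function(tok) {
      if (is_placeholder(tok)) return(tok)
      core <- strip_affixes(tok)
      if (!nzchar(core)) return(tok)
      repl <- if (grepl("[0-9]", core)) config$number_placeholder
              else if (tolower(core) %in% config$names) config$name_placeholder
              else return(tok)
      sub(core, repl, tok, fixed = TRUE)
    }, character(1L))
    paste(out, collapse = " ")
  }, character(1L), USE.NAMES = FALSE)
}

undouble <- function(stem) {
  n <- nchar(stem)
  if (n >= 3L) {
    last <- substr(stem, n, n)
    if (substr(stem, n - 1L, n - 1L) == last &&
        !last %in% c("a", "e", "i", "o", "u", "s", "l")) {
      return(substr(stem, 1L, n - 1L))
    }
  }
  stem
}

lemma_one <- function(tok, exc, dict) {
  if (is_placeholder(tok)) return(tok)
  if (tok %in% names(exc)) return(unname(exc[[tok]]))
  n <- nchar(tok)
  strip_vg <- function(suf) {
    stem <- substr(tok, 1L, n - nchar(suf))
    und <- undouble(stem)
    if (stem %in% dict) stem
    else if (und != stem && und %in% dict) und
    else if (paste0(stem, "e") %in% dict) paste0(stem, "e")
    else if (nchar(stem) < 3L) tok   # too short to be a stem
    else if (und != stem) und
    else stem
  }
  if (n >= 5L && endsWith(tok, "ing")) return(strip_vg("ing"))
  if (n > 4L && endsWith(tok, "ied")) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (n >= 4L && endsWith(tok, "ed")) return(strip_vg("ed"))
  if (n > 4L && endsWith(tok, "ies")) return(paste0(substr(tok, 1L, n - 3L), "y"))
  if (n > 3L && endsWith(tok, "es")) {
    stem_s <- substr(tok, 1L, n - 1L)   # drop just the final s
    stem_es <- substr(tok, 1L, n - 2L)
    if (stem_s %in% dict) return(stem_s)
    if (stem_es %in% dict) return(stem_es)
    if (grepl("(s|x|z|ch|sh)$", stem_es)) return(stem_es)
    return(stem_s)
  }
  if (n > 3L && endsWith(tok, "s") && !endsWith(tok, "ss") &&
      !endsWith(tok, "us") && !endsWith(tok, "is")) {
    return(substr(tok, 1L, n - 1L))
  }
  tok
}

#' Lemmatize lowercase tokens
#'
#' Irregular forms are mapped through the bundled exception table; regular
#' inflections (plural -s/-es/-ies, -ing, -ed) are stripped with consonant
#' undoubling and e-restoration validated against the dictionary.
#' Placeholders are returned unchanged.
#'
#' @param tokens Lowercase character vector.
#' @param config A [preprocess_config()].
#' @return Character vector of lemmas.
#' @export
#' @examples
#' lemmatize(c("sung", "helping", "sing"))
lemmatize <- function(tokens, config = preprocess_config()) {
  vapply(tokens, lemma_one, character(1L),
         exc = config$lemma_exceptions, dict = config$dictionary,
         USE.NAMES = FALSE)
}

#' Run the full preprocessing pipeline on texts
#'
#' Applies, in order: (1) case normalization, (2) spelling correction,
#' (3) name/number placeholder replacement, (4) punctuation removal,
#' (5) stopword removal, then lemmatization. A record may come out empty
#' (e.g. a text of pure punctuation); that is flagged, not an error.
#'
#' @param text Character vector of raw record texts.
#' @param config A [preprocess_config()].
#' @param freq Optional dictionary-frequency table for spelling tie-breaks.
#' @return A list of token vectors, one per input text, with attribute
#'   `empty`: a logical vector marking records with no surviving tokens.
#' @export
#' @examples
#' preprocess_text("Anna LOVES her drum!")[[1]]
preprocess_text <- function(text, config = preprocess_config(),
                            freq = NULL) {
  stopifnot(all(nzchar(text)))
  # lemmas of dictionary words count as valid so the pipeline is
  # idempotent on its own detokenized output
  dict2 <- unique(c(config$dictionary,
                    vapply(config$dictionary, lemma_one, character(1L),
                           exc = config$lemma_exceptions,
                           dict = config$dictionary, USE.NAMES = FALSE)))
  cfg <- config
  cfg$dictionary <- dict2
  lowered <- tolower(text)
  toks <- whitespace_tokenize(lowered)
  out <- lapply(toks, function(tk) {
    if (length(tk) == 0L) return(character(0L))
    cores <- vapply(tk, function(t) {
      if (is_placeholder(t)) "" else strip_affixes(t)
    }, character(1L), USE.NAMES = FALSE)
    fixed <- correct_spelling(cores, cfg, freq = freq)
    tk <- mapply(function(orig, core, fix) {
      if (nzchar(core) && core != fix) sub(core, fix, orig, fixed = TRUE)
      else orig
    }, tk, cores, fixed, USE.NAMES = FALSE)
    tk <- strsplit(replace_entities(paste(tk, collapse = " "), cfg),
                   "[[:space:]]+")[[1L]]
    tk <- vapply(tk, function(t) {
      if (grepl(cfg$name_placeholder, t, fixed = TRUE)) return(cfg$name_placeholder)
      if (grepl(cfg$number_placeholder, t, fixed = TRUE)) return(cfg$number_placeholder)
      gsub("[^a-z0-9]", "", t)
    }, character(1L), USE.NAMES = FALSE)
    tk <- tk[nzchar(tk)]
    tk <- tk[is_placeholder(tk) | !(tk %in% cfg$stopwords)]
    lemmatize(tk, cfg)
  })
  attr(out, "empty") <- lengths(out) == 0L
  out
}

#' Preprocess a whole corpus
#'
#' Convenience wrapper around [preprocess_text()] that extends the
#' spelling dictionary with the corpus vocabulary (so in-corpus spellings
#' are treated as valid) and supplies corpus token frequencies for
#' tie-breaking.
#'
#' @param corpus A `strategy_corpus`.
#' @param config A [preprocess_config()]; its dictionary is extended with
#'   the corpus vocabulary.
#' @return As [preprocess_text()], with additional attributes `id` and
#'   `label` copied from the corpus.
#' @export
preprocess_corpus <- function(corpus, config = preprocess_config()) {
  raw_tokens <- tolower(unlist(whitespace_tokenize(corpus$text)))
  cores <- unique(vapply(raw_tokens, strip_affixes, character(1L),
                         USE.NAMES = FALSE))
  cores <- cores[nzchar(cores) & !grepl("[0-9]", cores)]
  cfg <- config
  cfg$dictionary <- sort(unique(c(config$dictionary, cores)))
  freq <- table(vapply(raw_tokens, strip_affixes, character(1L),
                       USE.NAMES = FALSE))
  freq <- setNames(as.numeric(freq), names(freq))
  out <- preprocess_text(corpus$text, cfg, freq = freq)
  attr(out, "id") <- corpus$id
  attr(out, "label") <- corpus$label
  out
}
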