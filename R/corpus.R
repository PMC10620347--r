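# Synthetic-corpus generator.
#
# The study corpus (1,576 caregiver strategies) is not public; the only
# published statistics are per-class record counts, per-class mean lengths
# and overall token/vocabulary totals. The generator is calibrated to those
# aggregates and otherwise invents plausible structure: a fixed
# class-discriminative keyword pool per class, a shared non-discriminative
# vocabulary, short fixed refusal templates for the non-strategy class, and
# surface noise (misspellings, personal names, digits, punctuation,
# stopwords).

# Class keyword pools are fixed constants so that the bundled concept
# lexicon can share triggers with them. 40 per class.
class_keyword_pools <- function() {
  list(
    ENV = c("music", "quiet", "room", "schedule", "routine", "ramp",
            "headphones", "timer", "calendar", "chart", "picture", "visual",
            "space", "home", "school", "community", "teacher", "aide",
            "seating", "desk", "lighting", "noise", "reminder", "checklist",
            "equipment", "wheelchair", "rail", "door", "transport", "bus",
            "helper", "sibling", "peer", "group", "environment", "adapt",
            "modify", "arrange", "setup", "corner"),
    SELF = c("praise", "encourage", "confidence", "proud", "esteem",
             "identity", "emotion", "feeling", "calm", "reassure", "comfort",
             "affirm", "celebrate", "strength", "positive", "listen",
             "support", "trust", "belief", "worth", "accept", "belong",
             "respect", "courage", "motivate", "inspire", "value", "journal",
             "reflect", "mood", "anxiety", "fear", "confident", "happy",
             "pride", "success", "brave", "secure", "capable", "special"),
    PREF = c("choice", "choose", "favorite", "interest", "like", "love",
             "prefer", "option", "pick", "menu", "hobby", "game", "sport",
             "art", "craft", "animal", "dinosaur", "train", "lego",
             "drawing", "painting", "singing", "dancing", "swimming",
             "biking", "reading", "movie", "character", "color", "toy",
             "theme", "reward", "fun", "enjoy", "passion", "want", "wish",
             "select", "decide", "explore"),
    COMP = c("practice", "skill", "teach", "learn", "step", "instruction",
             "demonstrate", "model", "repeat", "drill", "master", "rehearse",
             "coach", "guide", "task", "goal", "progress", "improve",
             "ability", "competence", "lesson", "tutor", "exercise",
             "technique", "method", "breakdown", "sequence", "prompt", "cue",
             "scaffold", "feedback", "correct", "attempt", "try", "effort",
             "challenge", "level", "milestone", "achieve", "independent"),
    NONSTRAT = c("nothing", "none", "unsure", "unknown", "nobody", "never",
                 "issue", "problem", "difficulty", "struggle", "concern",
                 "worry", "hard", "unable", "cannot", "refuse", "avoid",
                 "quit", "stop", "rarely", "seldom", "barely", "hardly",
                 "without", "lack", "limited", "missing", "absent",
                 "question", "wonder", "maybe", "perhaps", "sometimes",
                 "depends", "varies", "unclear", "undecided", "waiting",
                 "idea", "anything")
  )
}

# fixed one-to-few-word refusal texts for the non-strategy class
refusal_templates <- function() {
  c("none", "no strategies needed", "nothing", "not applicable",
    "no adaptation described", "none at this time")
}

# common everyday words that head the shared (non-discriminative)
# vocabulary; the remainder is filled with pronounceable pseudo-words
common_shared_words <- function() {
  c("time", "day", "week", "morning", "evening", "night", "dinner", "lunch",
    "breakfast", "family", "friend", "child", "kid", "son", "daughter",
    "parent", "mom", "dad", "brother", "sister", "year", "month", "hour",
    "minute", "house", "yard", "park", "store", "car", "phone", "tablet",
    "computer", "book", "table", "chair", "bed", "bath", "clothes", "shoes",
    "food", "snack", "water", "walk", "run", "sit", "stand", "go", "come",
    "make", "take", "give", "get", "keep", "let", "ask", "tell", "say",
    "talk", "work", "play", "help", "use", "start", "finish", "plan",
    "find", "show", "watch", "wait", "stay", "leave", "visit", "join",
    "share", "bring", "put", "set", "open", "close", "turn", "call",
    "write", "read", "sing", "dance", "swim", "ride", "draw", "build",
    "clean", "cook", "eat", "drink", "sleep", "rest", "dress", "wash",
    "brush", "drive", "shop", "church", "class", "club", "team", "coach",
    "doctor", "therapy", "therapist", "session", "activity", "event",
    "party", "holiday", "weekend", "trip", "outing", "chore", "homework",
    "project", "little", "big", "new", "old", "good", "great", "nice",
    "easy", "slow", "fast", "early", "late", "first", "last", "next",
    "together", "alone", "outside", "inside", "around", "away", "often",
    "always", "usually", "really", "well", "better", "best", "again")
}

# deterministic pool of pronounceable pseudo-words, independent of any seed
pseudo_words <- function(n) {
  cons <- c("b", "d", "f", "g", "h", "j", "k", "l", "m",
            "n", "p", "r", "s", "t", "v", "w", "z")
  vows <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vows, paste0))   # 85 syllables
  two <- as.vector(outer(syl, syl, paste0))     # 7225 two-syllable stems
  # stride through the enumeration so neighbouring picks differ in both
  # syllables, then append a closing consonant for a word-like shape
  idx <- (seq_len(n) * 97L) %% length(two) + 1L
  paste0(two[idx], rep_len(c("n", "r", "s", "t", "l", "m", "k", ""), n))
}

# shared vocabulary: common words first, pseudo-words to fill
shared_vocabulary <- function(size) {
  base <- common_shared_words()
  if (size <= length(base)) return(base[seq_len(size)])
  c(base, pseudo_words(size - length(base)))
}

default_name_gazetteer_values <- function() {
  c("anna", "emma", "olivia", "ava", "sophia", "mia", "isabella", "amelia",
    "harper", "evelyn", "abigail", "emily", "ella", "lily", "grace", "chloe",
    "zoe", "nora", "hazel", "ruby", "liam", "noah", "oliver", "elijah",
    "william", "james", "benjamin", "lucas", "henry", "alexander", "mason",
    "michael", "ethan", "daniel", "jacob", "logan", "jackson", "levi",
    "sebastian", "mateo", "jack", "owen", "theodore", "aiden", "samuel",
    "joseph", "john", "david", "wyatt", "matthew", "luke", "asher", "carter",
    "julian", "grayson", "leo", "jayden", "gabriel", "isaac", "lincoln",
    "sarah", "rachel", "rebecca", "hannah", "leah", "naomi", "ruth",
    "esther", "maria", "elena", "sofia", "lucia", "carmen", "rosa", "diego",
    "carlos", "miguel", "jorge", "luis", "antonio")
}

#' Specification of a synthetic strategy corpus
#'
#' Returns the parameter object consumed by [generate_corpus()]. The
#' defaults reproduce the published aggregates of the study corpus: class
#' counts 975/307/84/104/106 (ENV/SELF/PREF/COMP/NONSTRAT, total 1,576) and
#' per-class mean lengths 7.20/6.60/7.64/5.85/5.21 tokens. Remaining
#' parameters (shared vocabulary size, keyword-pool size, discriminability,
#' noise rates) are calibration choices documented in the package vignette.
#'
#' @param class_counts Named integer vector of records per class.
#' @param mean_lengths Named numeric vector of expected tokens per class.
#' @param shared_vocab_size Number of non-discriminative vocabulary types.
#' @param keywords_per_class Size of each class-discriminative keyword pool
#'   (at most 40, the size of the fixed pools).
#' @param discriminability Probability in \[0,1\] that a content token is
#'   drawn from the record's class keyword pool rather than the shared
#'   vocabulary; 0 makes all classes textually identical by construction.
#' @param noise_rates Named list of per-token probabilities:
#'   `misspell_prob`, `name_prob`, `number_prob`, `punct_prob`,
#'   `stopword_prob`, each in \[0,1\].
#' @param refusal_prob Probability that a NONSTRAT record is one of the
#'   fixed refusal templates ("none", ...).
#' @param seed Integer RNG seed used by [generate_corpus()].
#' @return An object of class `corpus_spec`.
#' @export
#' @examples
#' sp <- corpus_spec()
#' sum(sp$class_counts)   # 1576
corpus_spec <- function(class_counts = c(ENV = 975, SELF = 307, PREF = 84,
                                         COMP = 104, NONSTRAT = 106),
                        mean_lengths = c(ENV = 7.20, SELF = 6.60,
                                         PREF = 7.64, COMP = 5.85,
                                         NONSTRAT = 5.21),
                        shared_vocab_size = 2000,
                        keywords_per_class = 40,
                        discriminability = 0.8,
                        noise_rates = list(misspell_prob = 0.05,
                                           name_prob = 0.05,
                                           number_prob = 0.05,
                                           punct_prob = 0.05,
                                           stopword_prob = 0.05),
                        refusal_prob = 0.3,
                        seed = 42) {
  cls <- strategy_classes()
  class_counts <- class_counts[cls]
  mean_lengths <- mean_lengths[cls]
  if (anyNA(class_counts) || any(class_counts < 0)) {
    stop("class_counts must be non-negative and cover all five classes")
  }
  if (anyNA(mean_lengths) || any(mean_lengths < 1)) {
    stop("mean_lengths must be >= 1 for all five classes")
  }
  probs <- c(unlist(noise_rates), discriminability = discriminability,
             refusal_prob = refusal_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  needed <- c("misspell_prob", "name_prob", "number_prob", "punct_prob",
              "stopword_prob")
  if (!all(needed %in% names(noise_rates))) {
    stop("noise_rates must name: ", paste(needed, collapse = ", "))
  }
  if (keywords_per_class < 0 || keywords_per_class > 40) {
    stop("keywords_per_class must be in 0..40")
  }
  structure(list(class_counts = class_counts,
                 mean_lengths = mean_lengths,
                 shared_vocab_size = as.integer(shared_vocab_size),
                 keywords_per_class = as.integer(keywords_per_class),
                 discriminability = discriminability,
                 noise_rates = noise_rates[needed],
                 refusal_prob = refusal_prob,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("Synthetic corpus specification\n")
  cat("  records:", paste(names(x$class_counts), x$class_counts,
                          sep = "=", collapse = " "),
      sprintf("(total %d)\n", sum(x$class_counts)))
  cat("  mean lengths:", paste(sprintf("%.2f", x$mean_lengths),
                               collapse = " "), "\n")
  cat(sprintf("  discriminability %.2f, refusal_prob %.2f, seed %d\n",
              x$discriminability, x$refusal_prob, x$seed))
  invisible(x)
}

misspell_token <- function(token) {
  letters_pool <- letters
  n <- nchar(token)
  op <- sample(c("sub", "ins", "del", "swap"), 1L)
  if (n < 2 && op %in% c("del", "swap")) op <- "ins"
  pos <- sample.int(n, 1L)
  chars <- strsplit(token, "")[[1]]
  switch(op,
    sub = paste0(c(chars[seq_len(pos - 1L)], sample(letters_pool, 1L),
                   chars[seq_len(n)[-seq_len(pos)]]), collapse = ""),
    ins = paste0(c(chars[seq_len(pos)], sample(letters_pool, 1L),
                   chars[seq_len(n)[-seq_len(pos)]]), collapse = ""),
    del = paste0(chars[-pos], collapse = ""),
    swap = {
      i <- min(pos, n - 1L)
      tmp <- chars[i]; chars[i] <- chars[i + 1L]; chars[i + 1L] <- tmp
      paste0(chars, collapse = "")
    })
}

generate_record_text <- function(label, spec, pools, shared, stopwords,
                                 gaz) {
  nr <- spec$noise_rates
  mu <- spec$mean_lengths[[label]]
  if (label == "NONSTRAT" && runif(1) < spec$refusal_prob) {
    return(sample(refusal_templates(), 1L))
  }
  if (label == "NONSTRAT") {
    # refusals are short, so non-refusal lengths are drawn with a
    # compensated mean keeping the class-level expectation on target
    ref_len <- mean(lengths(whitespace_tokenize(refusal_templates())))
    mu <- max(1, (mu - spec$refusal_prob * ref_len) /
                   (1 - spec$refusal_prob))
  }
  len <- 1L + rpois(1L, max(mu - 1, 0))
  pool <- pools[[label]]
  tokens <- character(len)
  for (i in seq_len(len)) {
    u <- runif(1)
    if (u < nr$stopword_prob) {
      tokens[i] <- sample(stopwords, 1L)
    } else if (u < nr$stopword_prob + nr$name_prob) {
      nm <- sample(gaz, 1L)
      substr(nm, 1L, 1L) <- toupper(substr(nm, 1L, 1L))
      tokens[i] <- nm
    } else if (u < nr$stopword_prob + nr$name_prob + nr$number_prob) {
      tokens[i] <- as.character(sample.int(60L, 1L))
    } else if (length(pool) > 0 && runif(1) < spec$discriminability) {
      tokens[i] <- sample(pool, 1L)
    } else {
      tokens[i] <- sample(shared, 1L)
    }
  }
  # surface noise applied after token choice
  for (i in seq_len(len)) {
    tok <- tokens[i]
    if (grepl("^[a-z]+$", tok) && runif(1) < nr$misspell_prob) {
      tok <- misspell_token(tok)
    }
    if (runif(1) < nr$punct_prob) {
      tok <- paste0(tok, sample(c(",", ".", "!"), 1L))
    }
    tokens[i] <- tok
  }
  if (runif(1) < 0.5) {
    substr(tokens[1L], 1L, 1L) <- toupper(substr(tokens[1L], 1L, 1L))
  }
  paste(tokens, collapse = " ")
}

#' Generate a labeled synthetic strategy corpus
#'
#' Draws a corpus of caregiver-strategy records under a [corpus_spec()].
#' Per-class record counts equal the spec exactly; record lengths follow a
#' shifted Poisson (1 + Poisson(mean - 1)); content tokens come from the
#' class keyword pool with probability `discriminability`, else from the
#' shared vocabulary; non-strategy records are fixed refusal templates with
#' probability `refusal_prob`; misspellings, personal names, digits,
#' punctuation and stopwords are injected at the configured rates. The same
#' seed yields a byte-identical corpus.
#'
#' @param spec A [corpus_spec()].
#' @return A `data.frame` of class `strategy_corpus` with columns `id`,
#'   `text`, `label`.
#' @export
#' @examples
#' sp <- corpus_spec(class_counts = c(ENV = 3, SELF = 0, PREF = 0,
#'                                    COMP = 0, NONSTRAT = 2))
#' generate_corpus(sp)
generate_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) stop("spec must be a corpus_spec")
  pools <- lapply(class_keyword_pools(),
                  function(p) p[seq_len(spec$keywords_per_class)])
  shared <- shared_vocabulary(spec$shared_vocab_size)
  stopwords <- default_stopwords()
  gaz <- default_name_gazetteer_values()
  labels <- rep(names(spec$class_counts), times = spec$class_counts)
  with_seed(spec$seed, {
    texts <- vapply(labels, function(lab) {
      generate_record_text(lab, spec, pools, shared, stopwords, gaz)
    }, character(1L), USE.NAMES = FALSE)
    out <- data.frame(id = sprintf("S%04d", seq_along(labels)),
                      text = texts, label = labels,
                      stringsAsFactors = FALSE)
    class(out) <- c("strategy_corpus", "data.frame")
    out
  })
}

#' @export
print.strategy_corpus <- function(x, ...) {
  cat(sprintf("Strategy corpus: %d records\n", nrow(x)))
  tab <- table(factor(x$label, levels = strategy_classes()))
  cat(" ", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  print(head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  invisible(x)
}

#' Descriptive statistics of a strategy corpus
#'
#' Token totals, vocabulary size (number of unique tokens) and mean record
#' lengths, overall and per class, under a supplied tokenizer.
#'
#' @param corpus A `strategy_corpus` (or data.frame with `text`, `label`).
#' @param tokenizer Function mapping a character vector of texts to a list
#'   of token vectors; defaults to whitespace splitting.
#' @return A list of class `corpus_stats`: `n_documents`, `n_tokens`,
#'   `vocab_size`, `mean_length_overall`, `mean_length_per_class`.
#' @export
corpus_stats <- function(corpus, tokenizer = whitespace_tokenize) {
  if (nrow(corpus) == 0L) stop("corpus is empty")
  toks <- tokenizer(corpus$text)
  lens <- lengths(toks)
  per_class <- vapply(split(lens, corpus$label), mean, numeric(1L))
  ord <- intersect(strategy_classes(), names(per_class))
  structure(list(n_documents = nrow(corpus),
                 n_tokens = sum(lens),
                 vocab_size = length(unique(unlist(toks))),
                 mean_length_overall = mean(lens),
                 mean_length_per_class = per_class[ord]),
            class = "corpus_stats")
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf("%d documents, %d tokens, vocabulary %d\n",
              x$n_documents, x$n_tokens, x$vocab_size))
  cat(sprintf("mean length %.2f overall;", x$mean_length_overall))
  cat(" per class:",
      paste(names(x$mean_length_per_class),
            sprintf("%.2f", x$mean_length_per_class),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read and write strategy corpora as tab-separated values
#'
#' The on-disk format is UTF-8 TSV with header `id`, `text`, `label` and
#' labels serialized as ENV/SELF/PREF/COMP/NONSTRAT.
#'
#' @param corpus A `strategy_corpus`.
#' @param path File path.
#' @return `read_corpus()` returns a `strategy_corpus`;
#'   `write_corpus()` returns `path` invisibly.
#' @export
write_corpus <- function(corpus, path) {
  if (any(grepl("\t", corpus$text))) stop("texts must not contain tabs")
  write.table(corpus[, c("id", "text", "label")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  out <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    encoding = "UTF-8", colClasses = "character")
  if (!all(c("id", "text", "label") %in% names(out))) {
    stop("corpus file must have columns id, text, label")
  }
  bad <- setdiff(unique(out$label), strategy_classes())
  if (length(bad) > 0L) stop("unknown labels in file: ",
                             paste(bad, collapse = ", "))
  class(out) <- c("strategy_corpus", "data.frame")
  out
}
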