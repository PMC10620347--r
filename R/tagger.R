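# Syntactic feature blocks: counts over the fixed Penn Treebank tagset and
# the universal dependency relation set. Taggers are pluggable; the
# bundled implementations are deterministic rule systems (closed-class
# lexicon + suffix rules; shallow head-finding for relations) so the
# package needs no external statistical model.

#' Fixed tagsets for the syntactic feature blocks
#'
#' `penn_tagset()` returns the 36 Penn Treebank part-of-speech tags;
#' `ud_relation_set()` the 37 universal dependency relations. Feature
#' vectors are counts over these fixed sets, so their length never varies
#' across documents.
#'
#' @return Character vector of tag names.
#' @export
penn_tagset <- function() {
  c("CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS", "MD",
    "NN", "NNS", "NNP", "NNPS", "PDT", "POS", "PRP", "PRP$", "RB", "RBR",
    "RBS", "RP", "SYM", "TO", "UH", "VB", "VBD", "VBG", "VBN", "VBP",
    "VBZ", "WDT", "WP", "WP$", "WRB")
}

#' @rdname penn_tagset
#' @export
ud_relation_set <- function() {
  c("acl", "advcl", "advmod", "amod", "appos", "aux", "case", "cc",
    "ccomp", "clf", "compound", "conj", "cop", "csubj", "dep", "det",
    "discourse", "dislocated", "expl", "fixed", "flat", "goeswith",
    "iobj", "list", "mark", "nmod", "nsubj", "nummod", "obj", "obl",
    "orphan", "parataxis", "punct", "reparandum", "root", "vocative",
    "xcomp")
}

tagger_lexicon <- function() {
  list(DT = c("the", "a", "an", "this", "that", "these", "those", "every",
              "each", "some", "any", "no"),
       PRP = c("i", "me", "we", "us", "you", "he", "him", "she", "her",
               "it", "they", "them", "myself", "himself", "herself",
               "itself", "themselves"),
       "PRP$" = c("my", "our", "your", "his", "its", "their", "hers",
                  "ours", "yours", "theirs"),
       IN = c("of", "in", "on", "at", "by", "for", "with", "about",
              "against", "between", "into", "through", "during", "before",
              "after", "above", "below", "from", "up", "down", "out",
              "off", "over", "under", "if", "because", "until", "while",
              "as"),
       CC = c("and", "but", "or", "nor", "so", "yet"),
       MD = c("can", "will", "would", "should", "could", "may", "might",
              "must", "shall"),
       WRB = c("when", "where", "why", "how"),
       WDT = c("which", "what"),
       WP = c("who", "whom"),
       EX = c("there"),
       UH = c("oh", "yes", "okay", "ok", "well"),
       RB = c("not", "never", "always", "often", "very", "too", "also",
              "here", "now", "then", "again", "usually", "really",
              "sometimes", "rarely", "seldom", "barely", "hardly",
              "daily", "maybe", "perhaps", "together", "alone"))
}

# verbs in base form recognized by the bundled tagger; covers the
# generator's verb vocabulary plus common English verbs
tagger_verb_lexicon <- function() {
  c("sing", "play", "help", "use", "make", "take", "give", "get", "keep",
    "let", "ask", "tell", "say", "talk", "work", "start", "finish",
    "plan", "find", "show", "watch", "wait", "stay", "leave", "visit",
    "join", "share", "bring", "put", "set", "open", "close", "turn",
    "call", "write", "read", "dance", "swim", "ride", "draw", "build",
    "clean", "cook", "eat", "drink", "sleep", "rest", "dress", "wash",
    "brush", "drive", "shop", "go", "come", "walk", "run", "sit",
    "stand", "practice", "teach", "learn", "repeat", "improve", "try",
    "choose", "pick", "prefer", "want", "wish", "select", "decide",
    "like", "love", "enjoy", "encourage", "praise", "reassure",
    "comfort", "affirm", "celebrate", "listen", "support", "trust",
    "accept", "belong", "respect", "motivate", "inspire", "reflect",
    "adapt", "modify", "arrange", "demonstrate", "model", "drill",
    "master", "rehearse", "coach", "guide", "prompt", "cue", "scaffold",
    "correct", "attempt", "achieve", "avoid", "refuse", "quit", "stop",
    "struggle", "wonder", "explore", "need", "be", "have", "do", "know",
    "see", "feel", "think", "wear", "grow", "buy", "catch", "speak")
}

#' Bundled rule-based part-of-speech tagger
#'
#' Assigns one Penn Treebank tag per token using, in order: placeholder
#' rules (`[name]` is NNP, `[number]` is CD), digit detection, a
#' closed-class lexicon, a base-verb lexicon, and suffix rules; the
#' fallback is NN.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @return Character vector of Penn Treebank tags, one per token.
#' @export
#' @examples
#' default_pos_tagger(c("[name]", "sing", "daily"))
default_pos_tagger <- function(tokens) {
  lex <- tagger_lexicon()
  verbs <- tagger_verb_lexicon()
  vapply(tokens, function(tok) {
    if (tok == "[name]") return("NNP")
    if (tok == "[number]") return("CD")
    if (grepl("^[0-9]+$", tok)) return("CD")
    for (tag in names(lex)) if (tok %in% lex[[tag]]) return(tag)
    if (tok %in% verbs) return("VB")
    n <- nchar(tok)
    if (n >= 5L && endsWith(tok, "ing")) return("VBG")
    if (n >= 4L && endsWith(tok, "ed")) return("VBD")
    if (n >= 4L && endsWith(tok, "ly")) return("RB")
    if (n >= 5L && endsWith(tok, "est")) return("JJS")
    if (grepl("(ous|ful|ive|able|ible)$", tok) && n >= 5L) return("JJ")
    if (n >= 4L && endsWith(tok, "er")) return("JJR")
    if (n >= 4L && endsWith(tok, "s") && !endsWith(tok, "ss")) return("NNS")
    "NN"
  }, character(1L), USE.NAMES = FALSE)
}

#' Part-of-speech tag count features
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param tagger Function mapping tokens to Penn Treebank tags; defaults
#'   to the bundled rule-based tagger. A plugged tagger emitting a tag
#'   outside the fixed tagset is an error.
#' @return Named numeric count vector of length `length(penn_tagset())`.
#' @export
pos_features <- function(tokens, tagger = default_pos_tagger) {
  tagset <- penn_tagset()
  out <- setNames(numeric(length(tagset)), tagset)
  if (length(tokens) == 0L) return(out)
  tags <- tagger(tokens)
  bad <- setdiff(unique(tags), tagset)
  if (length(bad) > 0L) {
    stop("tagger emitted unknown tag(s): ", paste(bad, collapse = ", "))
  }
  tab <- table(tags)
  out[names(tab)] <- as.numeric(tab)
  out
}

# shallow relation assignment from POS tags: first verb is the root (else
# the first token); nominals take nsubj before the root and obj after;
# modifiers map by tag class
default_dep_parser <- function(tokens, tags = default_pos_tagger(tokens)) {
  n <- length(tokens)
  if (n == 0L) return(character(0L))
  verbish <- tags %in% c("VB", "VBD", "VBG", "VBN", "VBP", "VBZ")
  root_i <- if (any(verbish)) which(verbish)[1L] else 1L
  rel <- character(n)
  for (i in seq_len(n)) {
    if (i == root_i) { rel[i] <- "root"; next }
    rel[i] <- switch(tags[i],
      DT = "det", CD = "nummod", JJ = "amod", JJR = "amod", JJS = "amod",
      RB = "advmod", RBR = "advmod", RBS = "advmod",
      IN = "case", TO = "mark", CC = "cc", MD = "aux",
      UH = "discourse", POS = "case",
      NN = , NNS = , NNP = , NNPS = , PRP =
        if (i < root_i) "nsubj" else "obj",
      "PRP$" = "nmod", WRB = "advmod", WDT = "det", WP = "nsubj",
      VB = , VBD = , VBG = , VBN = , VBP = , VBZ = "xcomp",
      "dep")
  }
  rel
}

#' Dependency relation count features
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param parser Function mapping tokens to universal dependency
#'   relations; defaults to the bundled shallow rule parser. Unknown
#'   relations from a plugged parser are an error.
#' @return Named numeric count vector of length
#'   `length(ud_relation_set())`.
#' @export
dep_features <- function(tokens, parser = default_dep_parser) {
  rels <- ud_relation_set()
  out <- setNames(numeric(length(rels)), rels)
  if (length(tokens) == 0L) return(out)
  got <- parser(tokens)
  bad <- setdiff(unique(got), rels)
  if (length(bad) > 0L) {
    stop("parser emitted unknown relation(s): ",
         paste(bad, collapse = ", "))
  }
  tab <- table(got)
  out[names(tab)] <- as.numeric(tab)
  out
}
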