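# Concept lexicon: a fixture emulating the manual mapping of strategy
# groups onto a biomedical metathesaurus. Each concept carries a strategy
# class, trigger keywords, a mapped/unmapped flag and (for mapped entries)
# a source-vocabulary tag. Concept assignment at run time is automated
# trigger matching; the original mapping was a manual expert process, so
# this is a documented fidelity gap, not a reproduction.

concept_name_patterns <- c(ENV = "adjustment of %s",
                           SELF = "support of %s",
                           PREF = "offering %s choices",
                           COMP = "training of %s")

#' Default concept lexicon
#'
#' A synthetic 71-entry concept lexicon distributed 38/15/12/6 across the
#' ENV/SELF/PREF/COMP classes, of which 49 are flagged as mapped to an
#' external vocabulary (the unmapped remainder is 12/6/3/1 per class).
#' Trigger keywords are drawn from the synthetic generator's class keyword
#' pools, so concept features are informative on generated corpora.
#'
#' @return A `data.frame` of class `concept_lexicon` with columns
#'   `concept`, `label`, `triggers` (comma-joined), `umls_mapped`,
#'   `source_vocabulary`.
#' @export
#' @examples
#' lex <- default_concept_lexicon()
#' nrow(lex)                  # 71
#' sum(lex$umls_mapped)       # 49
default_concept_lexicon <- function() {
  pools <- class_keyword_pools()
  n_per <- c(ENV = 38L, SELF = 15L, PREF = 12L, COMP = 6L)
  n_unmapped <- c(ENV = 12L, SELF = 6L, PREF = 3L, COMP = 1L)
  vocabs <- c("SNOMED_US", "CHV", "NOC", "PSY", "NIC", "RCD")
  rows <- lapply(names(n_per), function(cls) {
    kw <- pools[[cls]][seq_len(n_per[[cls]])]
    mapped <- rep(TRUE, n_per[[cls]])
    # the last entries of each class are the unmapped ones
    mapped[seq(n_per[[cls]] - n_unmapped[[cls]] + 1L, n_per[[cls]])] <- FALSE
    data.frame(concept = sprintf(concept_name_patterns[[cls]], kw),
               label = cls,
               triggers = kw,
               umls_mapped = mapped,
               source_vocabulary = ifelse(
                 mapped, rep_len(vocabs, n_per[[cls]]), NA_character_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("concept_lexicon", "data.frame")
  out
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(sprintf("Concept lexicon: %d concepts (%d mapped)\n",
              nrow(x), sum(x$umls_mapped)))
  print(table(factor(x$label, levels = setdiff(strategy_classes(),
                                               "NONSTRAT"))))
  invisible(x)
}

lexicon_triggers <- function(lexicon) {
  strsplit(lexicon$triggers, ",", fixed = TRUE)
}

#' Read and write a concept lexicon as tab-separated values
#'
#' Columns: `concept`, `label`, `triggers` (comma-joined),
#' `umls_mapped` (TRUE/FALSE), `source_vocabulary`.
#'
#' @param lexicon A `concept_lexicon`.
#' @param path File path.
#' @return `read_concept_lexicon()` returns a `concept_lexicon`;
#'   `write_concept_lexicon()` returns `path` invisibly.
#' @export
write_concept_lexicon <- function(lexicon, path) {
  write.table(lexicon, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_concept_lexicon
#' @export
read_concept_lexicon <- function(path) {
  out <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    encoding = "UTF-8")
  need <- c("concept", "label", "triggers", "umls_mapped",
            "source_vocabulary")
  if (!all(need %in% names(out))) {
    stop("lexicon file must have columns: ", paste(need, collapse = ", "))
  }
  out$umls_mapped <- as.logical(out$umls_mapped)
  if (any(!nzchar(out$triggers))) stop("every concept needs >= 1 trigger")
  class(out) <- c("concept_lexicon", "data.frame")
  out
}

#' Assign lexicon concepts to a preprocessed token sequence
#'
#' A concept is assigned iff any of its trigger keywords equals one of the
#' tokens. The result is deduplicated and ordered by lexicon order.
#'
#' @param tokens Character vector of preprocessed tokens.
#' @param lexicon A `concept_lexicon`.
#' @return Character vector of assigned concept names (possibly empty).
#' @export
assign_concepts <- function(tokens, lexicon = default_concept_lexicon()) {
  trig <- lexicon_triggers(lexicon)
  hit <- vapply(trig, function(tr) any(tr %in% tokens), logical(1L))
  unique(lexicon$concept[hit])
}
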