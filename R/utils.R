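# internal helpers shared across modules

# run `code` under a fixed RNG seed without clobbering the caller's stream
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# whitespace tokenizer used everywhere a tokenizer is not supplied
whitespace_tokenize <- function(text) {
  out <- strsplit(trimws(text), "[[:space:]]+")
  lapply(out, function(x) x[nzchar(x)])
}

# argmax with deterministic tie-break: first index among exact maxima,
# so ordering candidate columns lexicographically yields the
# lexicographically smallest label on ties
argmax_first <- function(x) which.max(x)

is_placeholder <- function(token) {
  grepl("^\\[.+\\]$", token)
}

read_wordfile <- function(name) {
  path <- system.file("extdata", name, package = "stratclass", mustWork = TRUE)
  readLines(path, encoding = "UTF-8", warn = FALSE)
}
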