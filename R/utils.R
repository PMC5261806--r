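# Internal helpers shared across modules.

# Coerce a single symbol string to a character vector of symbols.
# A length-1 character scalar is split into single characters; a longer
# character vector is taken as an already-tokenized symbol sequence (e.g.
# part-of-speech tags or the "10" token of the 1-10 digit task).
as_symbols <- function(x) {
  if (is.list(x) && length(x) == 1L) x <- x[[1L]]
  if (!is.character(x)) stop("symbol strings must be character vectors")
  if (length(x) == 1L && !is.na(x)) return(strsplit(x, "", fixed = TRUE)[[1L]])
  x
}

# Collapse a symbol vector for display / hashing. Multi-character symbols are
# joined with spaces so the collapsed form stays unambiguous.
collapse_symbols <- function(symbols, sep = NULL) {
  if (length(symbols) == 0L) return("")
  if (is.null(sep)) sep <- if (any(nchar(symbols) > 1L)) " " else ""
  paste(symbols, collapse = sep)
}

# Encode token sequences as single-character strings sharing one symbol map,
# so the C-level Levenshtein in utils::adist applies to arbitrary alphabets.
encode_for_adist <- function(seqs) {
  syms <- unique(unlist(seqs, use.names = FALSE))
  vapply(seqs, function(s) intToUtf8(match(s, syms) + 160L), character(1))
}

is_whole_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < 1e-8
}

# sample() that never falls into the 1:n surprise for length-1 vectors
sample_one <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]
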