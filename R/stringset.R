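#' Construct a string set
#'
#' A string set is the unit of transmission and of analysis: a collection of
#' symbol strings over a finite alphabet. Experiment sets hold the 15 unique
#' consonant strings passed between generations of learners; generic sets hold
#' any symbol-sequence collection (digit strings, part-of-speech tag
#' sequences) analysed with the same machinery.
#'
#' @param items Either a character vector (each element split into
#'   single-character symbols) or a list of character vectors, each vector an
#'   already-tokenized symbol sequence.
#' @param alphabet Optional character vector of permitted symbols. Defaults to
#'   the sorted set of symbols occurring in `items`.
#' @param kind `"experiment"` for transmitted consonant sets (symbols are
#'   case-normalized to uppercase) or `"generic"` for everything else.
#' @return An object of class `string_set` with fields `items` (list of symbol
#'   vectors), `alphabet`, `kind` and `sep` (the separator used to display
#'   items: `""` for single-character symbols, `" "` for token symbols).
#' @examples
#' string_set(c("CMC", "SFL", "PCS"), kind = "experiment")
#' @export
string_set <- function(items, alphabet = NULL, kind = c("generic", "experiment")) {
  kind <- match.arg(kind)
  if (is.character(items)) {
    items <- lapply(items, function(x) strsplit(x, "", fixed = TRUE)[[1L]])
  }
  if (!is.list(items)) stop("`items` must be a character vector or a list of symbol vectors")
  items <- lapply(items, as.character)
  if (kind == "experiment") items <- lapply(items, toupper)
  if (any(lengths(items) < 1L)) stop("every item must contain at least one symbol")
  used <- unique(unlist(items, use.names = FALSE))
  if (is.null(alphabet)) {
    alphabet <- sort(used)
  } else {
    alphabet <- as.character(alphabet)
    if (kind == "experiment") alphabet <- toupper(alphabet)
    if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
    if (!all(used %in% alphabet)) {
      stop("items contain symbols outside the declared alphabet: ",
           paste(setdiff(used, alphabet), collapse = ", "))
    }
  }
  # the display/fragment separator is a set-level property of the alphabet,
  # so fragment keys stay consistent across items of one set
  sep <- if (length(alphabet) && any(nchar(alphabet) > 1L)) " " else ""
  structure(list(items = items, alphabet = alphabet, kind = kind, sep = sep),
            class = "string_set")
}

#' Coerce to a string set
#'
#' @param x A `string_set`, a character vector of strings, or a list of symbol
#'   vectors.
#' @param ... Passed on to [string_set()].
#' @return A `string_set`.
#' @export
as_string_set <- function(x, ...) {
  if (inherits(x, "string_set")) return(x)
  string_set(x, ...)
}

#' @export
length.string_set <- function(x) length(x$items)

#' @export
as.character.string_set <- function(x, ...) {
  vapply(x$items, collapse_symbols, character(1), sep = x$sep)
}

#' @export
`[.string_set` <- function(x, i) {
  out <- x
  out$items <- x$items[i]
  out
}

#' @export
print.string_set <- function(x, ...) {
  cat(sprintf("<string_set: %d items, alphabet {%s}, kind=%s>\n",
              length(x), paste(x$alphabet, collapse = ","), x$kind))
  strs <- as.character(x)
  show <- head(strs, 15L)
  cat(" ", paste(show, collapse = ", "))
  if (length(strs) > 15L) cat(sprintf(", ... (%d more)", length(strs) - 15L))
  cat("\n")
  invisible(x)
}

#' Item lengths of a string set
#'
#' @param s A `string_set` (or coercible).
#' @return Integer vector of symbol counts per item.
#' @export
item_lengths <- function(s) {
  s <- as_string_set(s)
  lengths(s$items)
}

#' Remap the symbols of a string set
#'
#' Applies a bijective substitution of the alphabet, as done between test
#' sessions of a transmission chain to strip surface regularities (acronyms,
#' keyboard layout) while preserving all structural properties: string
#' lengths, within-set edit distances, fragment-count profiles and
#' reuse-network topology are identical before and after.
#'
#' @param s A `string_set`.
#' @param mapping Named character vector; names are current symbols, values
#'   the replacement symbols. Must be injective and cover the alphabet of `s`.
#' @param reject_words Optional character vector of forbidden surface forms
#'   (e.g. an acronym/word list); an error is raised if any remapped item
#'   matches one. This approximates the human screening of remapped sets.
#' @return The remapped `string_set`.
#' @examples
#' s <- string_set(c("CMC", "SFL"), kind = "experiment")
#' remap_symbols(s, c(C = "K", M = "T", S = "B", F = "D", L = "N"))
#' @export
remap_symbols <- function(s, mapping, reject_words = NULL) {
  s <- as_string_set(s)
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    stop("`mapping` must be a named character vector (old symbol -> new symbol)")
  }
  mapping <- setNames(as.character(mapping), names(mapping))
  if (s$kind == "experiment") {
    mapping <- setNames(toupper(mapping), toupper(names(mapping)))
  }
  missing <- setdiff(s$alphabet, names(mapping))
  if (length(missing)) {
    stop("mapping does not cover symbols: ", paste(missing, collapse = ", "))
  }
  mapping <- mapping[s$alphabet]
  if (anyDuplicated(mapping)) {
    stop("mapping is not injective on the alphabet (two symbols map to one target)")
  }
  out <- s
  out$items <- lapply(s$items, function(sym) unname(mapping[sym]))
  out$alphabet <- sort(unname(mapping))
  if (!is.null(reject_words)) {
    strs <- vapply(out$items, collapse_symbols, character(1), sep = out$sep)
    hits <- strs[strs %in% toupper(reject_words)]
    if (length(hits)) {
      stop("remapping produces forbidden surface forms: ",
           paste(unique(hits), collapse = ", "))
    }
  }
  out
}

#' Draw a random bijective remapping of a string set
#'
#' @param s A `string_set`.
#' @param pool Character vector of target symbols to draw from; defaults to
#'   the 20 uppercase English keyboard consonants used in the recall
#'   experiment.
#' @param seed Optional integer seed for reproducibility.
#' @param reject_words,max_tries Optional screening as in [remap_symbols()]:
#'   redraw (up to `max_tries` times) until no remapped item matches a word.
#' @return The remapped `string_set`, with the mapping in attribute
#'   `"mapping"`.
#' @export
random_remap <- function(s, pool = keyboard_consonants(), seed = NULL,
                         reject_words = NULL, max_tries = 1000L) {
  s <- as_string_set(s)
  if (length(pool) < length(s$alphabet)) stop("target pool smaller than alphabet")
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    mapping <- setNames(sample(pool, length(s$alphabet)), s$alphabet)
    out <- tryCatch(remap_symbols(s, mapping, reject_words = reject_words),
                    error = function(e) NULL)
    if (!is.null(out)) return(structure(out, mapping = mapping))
  }
  stop("no acceptable remapping found in ", max_tries, " tries")
}

#' The 20 consonant characters of an English keyboard
#'
#' The symbol pool from which experiment alphabets and remapping targets are
#' drawn (Y is conventionally excluded as a semi-vowel).
#'
#' @return Character vector of 20 uppercase consonants.
#' @export
keyboard_consonants <- function() {
  setdiff(LETTERS, c("A", "E", "I", "O", "U", "Y"))
}

#' Filter a string set by item length
#'
#' @param s A `string_set` (or coercible).
#' @param min_len,max_len Inclusive bounds on item length in symbols.
#' @return A `string_set` containing exactly the items within the bounds,
#'   original order preserved (possibly empty).
#' @examples
#' filter_by_length(c("AB", "ABC", "ABCDEF", "ABCDEFG"), 3, 6)
#' @export
filter_by_length <- function(s, min_len = 1L, max_len = Inf) {
  if (min_len > max_len) stop("`min_len` must not exceed `max_len`")
  s <- as_string_set(s)
  keep <- lengths(s$items) >= min_len & lengths(s$items) <= max_len
  out <- s
  out$items <- s$items[keep]
  out
}
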