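#' Validate an initial (generation-0) experiment string set
#'
#' Initial sets of the recall experiment are tightly constrained so that no
#' sequential structure is present at the outset: 15 unique strings (5 each of
#' lengths 3, 4 and 5), an alphabet of exactly 6 consonants each appearing 10
#' times (60 symbols in total), and near-uniform fragment frequencies capped
#' at 3 occurrences of any bigram and 2 of any trigram. Fragment repetitions
#' are counted as token counts of contiguous within-string n-grams, pooled
#' across the whole set.
#'
#' @param s A `string_set` of kind `"experiment"` (or coercible).
#' @param n_items,per_length,lengths,alphabet_size,symbol_count,max_bigram,max_trigram
#'   The design constants; defaults are the published design (15 items, 5 per
#'   length in 3:5, 6 symbols at 10 occurrences, caps 3 and 2).
#' @return A `validation_report`: per-constraint booleans in `$checks`,
#'   offending counts (`n_items`, `length_histogram`, `symbol_counts`,
#'   `max_bigram_repetition`, `max_trigram_repetition`, `total_symbols`), and
#'   `$passes`, the conjunction of all checks.
#' @examples
#' validate_initial_set(initial_string_set(1))$passes
#' @export
validate_initial_set <- function(s, n_items = 15L, per_length = 5L, lengths = 3:5,
                                 alphabet_size = 6L, symbol_count = 10L,
                                 max_bigram = 3L, max_trigram = 2L) {
  s <- as_string_set(s, kind = "experiment")
  if (s$kind != "experiment") stop("validation applies to experiment string sets")
  if (length(s) == 0L) stop("cannot validate an empty string set")
  strs <- as.character(s)
  lens <- lengths(s$items)
  symbols <- unlist(s$items, use.names = FALSE)
  symbol_counts <- table(factor(symbols, levels = sort(unique(symbols))))
  len_hist <- table(factor(lens, levels = sort(unique(c(lengths, lens)))))
  bi <- unlist(lapply(s$items, ngrams, n = 2L), use.names = FALSE)
  tri <- unlist(lapply(s$items, ngrams, n = 3L), use.names = FALSE)
  max_bi <- if (length(bi)) max(table(bi)) else 0L
  max_tri <- if (length(tri)) max(table(tri)) else 0L

  checks <- c(
    n_items = length(s) == n_items,
    items_unique = !anyDuplicated(strs),
    length_histogram = all(len_hist[as.character(lengths)] == per_length) &&
      sum(len_hist) == length(s) && all(lens %in% lengths),
    alphabet_size = length(symbol_counts) == alphabet_size,
    symbol_uniformity = all(symbol_counts == symbol_count),
    total_symbols = length(symbols) == alphabet_size * symbol_count,
    max_bigram = max_bi <= max_bigram,
    max_trigram = max_tri <= max_trigram
  )
  structure(list(
    checks = checks,
    passes = all(checks),
    n_items = length(s),
    length_histogram = len_hist,
    symbol_counts = symbol_counts,
    total_symbols = length(symbols),
    max_bigram_repetition = as.integer(max_bi),
    max_trigram_repetition = as.integer(max_tri)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s>\n", if (x$passes) "PASS" else "FAIL"))
  for (nm in names(x$checks)) {
    cat(sprintf("  %-18s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAIL"))
  }
  cat(sprintf("  items=%d symbols=%d max_bigram=%d max_trigram=%d\n",
              x$n_items, x$total_symbols,
              x$max_bigram_repetition, x$max_trigram_repetition))
  invisible(x)
}

#' Generate a constrained initial string set
#'
#' Rejection sampling with restart: a multiset of 60 symbols (10 copies of
#' each of the 6 alphabet symbols) is shuffled into the fifteen length slots
#' (5 each of lengths 3, 4, 5) and the candidate is accepted iff it satisfies
#' [validate_initial_set()]. This yields sets that are random yet unstructured,
#' with near-uniform bigram and trigram frequencies.
#'
#' @param alphabet Character vector of 6 distinct symbols.
#' @param seed Optional integer seed; the same alphabet and seed always yield
#'   the same set.
#' @param max_restarts Maximum number of rejection-sampling attempts before
#'   giving up with an error reporting the attempt count.
#' @return A valid `string_set` of kind `"experiment"`, with the number of
#'   attempts used in attribute `"attempts"`.
#' @examples
#' s <- generate_initial_set(c("B", "C", "D", "F", "G", "H"), seed = 1)
#' validate_initial_set(s)$passes
#' @export
generate_initial_set <- function(alphabet, seed = NULL, max_restarts = 100000L) {
  alphabet <- toupper(as.character(alphabet))
  if (length(alphabet) != 6L || anyDuplicated(alphabet)) {
    stop("`alphabet` must contain exactly 6 distinct symbols")
  }
  if (!is.null(seed)) set.seed(seed)
  slot_lengths <- rep(3:5, each = 5L)
  pool <- rep(alphabet, each = 10L)
  ends <- cumsum(slot_lengths)
  starts <- ends - slot_lengths + 1L
  for (attempt in seq_len(max_restarts)) {
    shuffled <- sample(pool)
    items <- lapply(seq_along(slot_lengths), function(i) shuffled[starts[i]:ends[i]])
    cand <- string_set(items, alphabet = alphabet, kind = "experiment")
    rep_ok <- validate_initial_set(cand)
    if (rep_ok$passes) return(structure(cand, attempts = attempt))
  }
  stop("no valid initial set found after ", max_restarts, " attempts")
}

#' The eight published initial string sets
#'
#' The generation-0 seed sets of the eight transmission chains, shipped as
#' plain-text fixtures and parsed on demand.
#'
#' @param chain Chain number, 1 to 8.
#' @return `initial_string_set()` returns one `string_set`;
#'   `initial_string_sets()` returns a named list of all eight.
#' @examples
#' initial_string_set(2)
#' @export
initial_string_set <- function(chain) {
  if (!is_whole_number(chain) || chain < 1 || chain > 8) {
    stop("`chain` must be an integer between 1 and 8")
  }
  path <- system.file("extdata", "initial_sets",
                      sprintf("chain%d.txt", as.integer(chain)),
                      package = "seqchains", mustWork = TRUE)
  read_string_set(path, kind = "experiment")
}

#' @rdname initial_string_set
#' @export
initial_string_sets <- function() {
  setNames(lapply(1:8, initial_string_set), paste0("chain", 1:8))
}
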