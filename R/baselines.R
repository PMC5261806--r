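#' Treat a non-negative integer as a digit string
#'
#' Word-frequency counts (and similar quantities) are turned into symbol
#' strings by taking their decimal digit expansion, e.g. a frequency of
#' 215686 becomes the length-6 string "215686".
#'
#' @param n Non-negative whole number(s), or strings of digits.
#' @return Character vector of digit strings.
#' @examples
#' digit_string(215686)
#' @export
digit_string <- function(n) {
  if (is.character(n)) {
    if (any(!grepl("^[0-9]+$", n))) stop("digit strings must contain digits only")
    return(n)
  }
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0) ||
      any(abs(n - round(n)) > 1e-8)) {
    stop("`n` must be non-negative whole numbers")
  }
  trimws(format(round(n), scientific = FALSE, trim = TRUE))
}

#' Extract digit runs from passwords
#'
#' Pulls the maximal contiguous runs of digits out of each password, in
#' left-to-right order; passwords without digits contribute nothing.
#' Length-1 runs are retained (they become isolated nodes in a reuse
#' network, having no bigrams).
#'
#' @param passwords Character vector.
#' @return Character vector of all digit runs, pooled in input order.
#' @examples
#' password_digit_runs("abc123def45") # "123" "45"
#' @export
password_digit_runs <- function(passwords) {
  if (!is.character(passwords)) stop("`passwords` must be character")
  runs <- regmatches(passwords, gregexpr("[0-9]+", passwords))
  unlist(runs, use.names = FALSE)
}

#' A stream of digit symbols
#'
#' A single long symbol sequence, e.g. the concatenated output of a
#' random-number generation task, from which comparison string sets are
#' resampled with [sample_windows()].
#'
#' @param symbols Character vector of digit symbols (each element one symbol;
#'   `"10"` is a single token in the 1-10 task mode), or one unseparated
#'   digit string.
#' @param provenance Free-text label.
#' @return A `digit_stream`.
#' @export
digit_stream <- function(symbols, provenance = "stream") {
  symbols <- as_symbols(symbols)
  if (length(symbols) < 1L) stop("the stream is empty")
  structure(list(symbols = symbols, provenance = provenance),
            class = "digit_stream")
}

#' @export
length.digit_stream <- function(x) length(x$symbols)

#' @export
print.digit_stream <- function(x, ...) {
  cat(sprintf("<digit_stream: %d symbols, %s>\n", length(x), x$provenance))
  invisible(x)
}

#' Resample windows from a digit stream
#'
#' Draws `n` contiguous windows from the stream, window lengths uniform over
#' `lengths` and start positions uniform over the feasible range (windows may
#' overlap). This mirrors segmenting a long human-generated digit sequence
#' into experiment-sized strings.
#'
#' @param stream A [digit_stream()] (or a symbol vector / single string).
#' @param n Number of windows (>= 1).
#' @param lengths Window lengths to draw from (default 3:6).
#' @param seed Optional integer seed.
#' @return A `string_set` of kind `"generic"`; every item is a contiguous
#'   substring of the stream.
#' @export
sample_windows <- function(stream, n, lengths = 3:6, seed = NULL) {
  if (!inherits(stream, "digit_stream")) stream <- digit_stream(stream)
  if (!is_whole_number(n) || n < 1) stop("`n` must be a positive integer")
  if (length(stream) < max(lengths)) {
    stop("stream of length ", length(stream),
         " is shorter than the longest requested window (", max(lengths), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  L <- sample(rep(lengths, length.out = max(2L, length(lengths))), n, replace = TRUE)
  L <- L[seq_len(n)]
  items <- lapply(L, function(l) {
    start <- sample.int(length(stream) - l + 1L, 1L)
    stream$symbols[start:(start + l - 1L)]
  })
  string_set(items, alphabet = sort(unique(stream$symbols)), kind = "generic")
}
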