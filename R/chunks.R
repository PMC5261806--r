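#' Contiguous n-gram fragments of a symbol string
#'
#' `ngrams()` returns the contiguous n-grams of one order; `fragments()`
#' returns the chunk inventory used by Associative Chunk Strength: for a
#' string of `x` bigrams, all `x` bigrams followed by all `x - 1` trigrams,
#' in left-to-right order. A length-2 string contributes a single bigram and
#' no trigram; a length-1 string has no fragments.
#'
#' @param x A symbol string (character scalar or token vector).
#' @param n Fragment orders to extract (default bigrams then trigrams).
#' @param sep Separator joining symbols in the fragment keys: `""` for
#'   single-character symbols, `" "` for token symbols. Default (`NULL`)
#'   chooses by inspecting `x`; set-level callers pass their set's separator
#'   so that keys stay consistent across items.
#' @return Character vector of fragments.
#' @examples
#' fragments("ZVX") # "ZV" "VX" "ZVX"
#' @export
fragments <- function(x, n = 2:3, sep = NULL) {
  sym <- as_symbols(x)
  unlist(lapply(sort(n), function(k) ngrams(sym, k, sep = sep)),
         use.names = FALSE)
}

#' @rdname fragments
#' @export
ngrams <- function(x, n, sep = NULL) {
  sym <- as_symbols(x)
  L <- length(sym)
  if (L < n) return(character(0))
  if (is.null(sep)) sep <- if (any(nchar(sym) > 1L)) " " else ""
  vapply(seq_len(L - n + 1L),
         function(i) paste(sym[i:(i + n - 1L)], collapse = sep),
         character(1))
}

#' Fragment frequency table of a training set
#'
#' Pools the bigram/trigram fragments of every training item into a frequency
#' table. Three normalization modes are supported: `"raw_count"` (token
#' counts pooled over items), `"per_item_norm"` (token counts divided by the
#' number of training items; the package default for Associative Chunk
#' Strength) and `"presence_prop"` (proportion of items containing the
#' fragment at least once).
#'
#' @param training A nonempty `string_set` (or coercible).
#' @param mode Normalization mode.
#' @param exposures Exposure multiplier for the count-based modes (e.g. the
#'   number of training blocks in which each item is seen); must be 1 under
#'   `"presence_prop"`.
#' @param n Fragment orders, passed to [fragments()].
#' @return A `fragment_table`: `$counts` (named numeric), `$n_items`,
#'   `$mode`, `$exposures`.
#' @examples
#' fragment_table("ZVX", mode = "raw_count")$counts
#' @export
fragment_table <- function(training,
                           mode = c("per_item_norm", "raw_count", "presence_prop"),
                           exposures = 1, n = 2:3) {
  mode <- match.arg(mode)
  training <- as_string_set(training)
  if (length(training) == 0L) stop("training set is empty")
  if (!is.numeric(exposures) || length(exposures) != 1L || exposures < 1) {
    stop("`exposures` must be a single number >= 1")
  }
  if (mode == "presence_prop" && exposures != 1) {
    stop("`exposures` has no meaning for presence proportions; leave it at 1")
  }
  per_item <- lapply(training$items, fragments, n = n, sep = training$sep)
  counts <- switch(mode,
    raw_count = ,
    per_item_norm = {
      tab <- table(unlist(per_item, use.names = FALSE))
      v <- as.numeric(tab) * exposures
      if (mode == "per_item_norm") v <- v / length(training)
      setNames(v, names(tab))
    },
    presence_prop = {
      tab <- table(unlist(lapply(per_item, unique), use.names = FALSE))
      setNames(as.numeric(tab) / length(training), names(tab))
    }
  )
  structure(list(counts = counts, n_items = length(training),
                 mode = mode, exposures = exposures),
            class = "fragment_table")
}

#' @export
print.fragment_table <- function(x, ...) {
  cat(sprintf("<fragment_table: %d fragments over %d items, mode=%s%s>\n",
              length(x$counts), x$n_items, x$mode,
              if (x$exposures != 1) sprintf(", exposures=%g", x$exposures) else ""))
  invisible(x)
}

#' Associative Chunk Strength
#'
#' The ACS of a test string is the mean training-table frequency of its
#' fragments: the sum of the frequencies of its bigrams and trigrams divided
#' by the number of fragments (e.g. for ZVX, the frequencies of ZV, VX and
#' ZVX divided by 3). Fragments absent from the training table contribute 0.
#' `acs_global()` averages the per-item ACS over all test items, giving a
#' set-level measure of how much the test set reuses the training set's
#' chunks.
#'
#' @param test A symbol string of length >= 2 (`acs_item`) or a nonempty
#'   string set (`acs_global`).
#' @param table A [fragment_table()] built from the training set.
#' @param on_short What to do with strings shorter than 2 symbols, which have
#'   no fragments: `"error"` (default) or `"zero"`.
#' @return A non-negative score (unitless; its scale depends on the table's
#'   normalization mode).
#' @examples
#' acs_item("ZVX", fragment_table("ZVX", mode = "raw_count")) # 1
#' @export
acs_item <- function(test, table, on_short = c("error", "zero")) {
  on_short <- match.arg(on_short)
  if (!inherits(table, "fragment_table")) stop("`table` must be a fragment_table")
  sym <- as_symbols(test)
  if (length(sym) < 2L) {
    if (on_short == "error") {
      stop("ACS is undefined for strings shorter than 2 symbols")
    }
    return(0)
  }
  sep <- if (any(grepl(" ", names(table$counts), fixed = TRUE))) " " else NULL
  fr <- fragments(sym, sep = sep)
  v <- table$counts[fr]
  v[is.na(v)] <- 0
  mean(v)
}

#' @rdname acs_item
#' @param training The training string set (generation *n - 1*).
#' @param mode,exposures Passed to [fragment_table()].
#' @export
acs_global <- function(training, test,
                       mode = c("per_item_norm", "raw_count", "presence_prop"),
                       exposures = 1, on_short = c("error", "zero")) {
  mode <- match.arg(mode)
  test <- as_string_set(test)
  if (length(test) == 0L) stop("test set is empty")
  tab <- fragment_table(training, mode = mode, exposures = exposures)
  mean(vapply(test$items, acs_item, numeric(1), table = tab, on_short = on_short))
}
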