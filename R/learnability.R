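#' Levenshtein edit distance between two symbol strings
#'
#' Minimum number of single-symbol insertions, deletions or substitutions
#' (unit costs) turning one string into the other. Accepts plain character
#' scalars (split into single-character symbols) or token vectors (e.g.
#' part-of-speech tag sequences); empty strings are permitted.
#'
#' @param a,b Symbol strings.
#' @return Non-negative integer edit count.
#' @examples
#' edit_distance("QZM", "QZV") # 1
#' @export
edit_distance <- function(a, b) {
  a <- as_symbols(a)
  b <- as_symbols(b)
  enc <- encode_for_adist(list(a, b))
  as.integer(adist(enc[1L], enc[2L]))
}

# All pairwise edit distances between two collections of symbol vectors,
# through one shared symbol encoding and a single adist call.
edit_distance_matrix <- function(items_a, items_b) {
  enc <- encode_for_adist(c(items_a, items_b))
  na <- length(items_a)
  m <- adist(enc[seq_len(na)], enc[-seq_len(na)])
  storage.mode(m) <- "integer"
  m
}

#' Normalized edit distance
#'
#' Two normalizations of the Levenshtein distance to the unit interval are
#' provided. `"max"` (the default used throughout the learnability scoring)
#' divides the raw distance by the longer of the two lengths. `"path"` is the
#' Marzal-Vidal path-normalized distance: the minimum over edit paths of the
#' path weight divided by the path length, computed by dynamic programming
#' over paths of each feasible length.
#'
#' @param a,b Symbol strings.
#' @param method `"max"` or `"path"`.
#' @return A value in `[0, 1]`; 0 for two empty strings.
#' @export
normalized_edit_distance <- function(a, b, method = c("max", "path")) {
  method <- match.arg(method)
  a <- as_symbols(a)
  b <- as_symbols(b)
  if (length(a) == 0L && length(b) == 0L) return(0)
  if (method == "max") {
    edit_distance(a, b) / max(length(a), length(b))
  } else {
    mv_distance(a, b)
  }
}

# Marzal-Vidal path-normalized edit distance, unit costs.
# C[i+1, j+1, l+1] = minimal weight of an edit path with exactly l operations
# from (0,0) to (i,j); answer = min over feasible l of C[m+1, n+1, l+1] / l.
mv_distance <- function(a, b) {
  m <- length(a)
  n <- length(b)
  if (m == 0L && n == 0L) return(0)
  lmax <- m + n
  C <- array(Inf, dim = c(m + 1L, n + 1L, lmax + 1L))
  C[1L, 1L, 1L] <- 0
  for (l in seq_len(lmax)) {
    for (i in 0:m) {
      for (j in 0:n) {
        if (i + j < l || max(i, j) > l) next
        best <- Inf
        if (i > 0L && j > 0L) {
          best <- C[i, j, l] + (a[i] != b[j])
        }
        if (i > 0L) best <- min(best, C[i, j + 1L, l] + 1)
        if (j > 0L) best <- min(best, C[i + 1L, j, l] + 1)
        C[i + 1L, j + 1L, l + 1L] <- best
      }
    }
  }
  ls <- max(m, n):lmax
  min(C[m + 1L, n + 1L, ls + 1L] / ls)
}

#' Closest training item to a recalled test string
#'
#' Scans the training set for an item minimizing the edit distance to the
#' test string. Ties are broken deterministically in favour of the
#' lexicographically smallest training item; the reported distance is
#' unaffected by the tie-break. Matching is independent per test item: one
#' training item may be closest to several test strings.
#'
#' @param test A symbol string.
#' @param training A nonempty `string_set` (or coercible).
#' @return List with `item` (the closest training string, collapsed) and
#'   `distance` (integer edits).
#' @examples
#' closest_training_item("QZM", c("QZV", "ABCDE", "FFFFF"))
#' @export
closest_training_item <- function(test, training) {
  training <- as_string_set(training)
  if (length(training) == 0L) stop("training set is empty")
  test <- as_symbols(test)
  d <- edit_distance_matrix(list(test), training$items)[1L, ]
  strs <- as.character(training)
  cand <- which(d == min(d))
  pick <- cand[order(strs[cand])][1L]
  list(item = strs[pick], distance = d[pick])
}

#' Score a recalled string set against its training set
#'
#' Each test (recalled) string is matched to its closest training item by
#' Levenshtein distance; the per-item error is the normalized distance to
#' that item. Set-level summaries are the global error (mean normalized
#' error), the number of exactly recalled items and the mean string length of
#' the test set.
#'
#' @param training,test Nonempty `string_set`s (or coercibles); `training` is
#'   generation *n*, `test` the recalled generation *n + 1*.
#' @param normalize Normalization of the per-item error, see
#'   [normalized_edit_distance()].
#' @return A `recall_score`: `$items` (data frame with `test`, `closest`,
#'   `edits`, `normalized_error`), `$global_error`, `$n_correct`,
#'   `$mean_length`.
#' @examples
#' recall_score(c("ABCD", "EFGH"), c("ABCE", "EFGH"))
#' @export
recall_score <- function(training, test, normalize = c("max", "path")) {
  normalize <- match.arg(normalize)
  training <- as_string_set(training)
  test <- as_string_set(test)
  if (length(training) == 0L || length(test) == 0L) {
    stop("training and test sets must be nonempty")
  }
  train_strs <- as.character(training)
  d <- edit_distance_matrix(test$items, training$items)
  closest <- character(length(test))
  edits <- integer(length(test))
  nerr <- numeric(length(test))
  for (i in seq_along(test$items)) {
    cand <- which(d[i, ] == min(d[i, ]))
    pick <- cand[order(train_strs[cand])][1L]
    closest[i] <- train_strs[pick]
    edits[i] <- d[i, pick]
    nerr[i] <- if (normalize == "max") {
      if (edits[i] == 0L) 0 else
        edits[i] / max(length(test$items[[i]]), length(training$items[[pick]]))
    } else {
      mv_distance(test$items[[i]], training$items[[pick]])
    }
  }
  structure(list(
    items = data.frame(test = as.character(test), closest = closest,
                       edits = edits, normalized_error = nerr,
                       stringsAsFactors = FALSE),
    global_error = mean(nerr),
    n_correct = sum(as.character(test) %in% train_strs),
    mean_length = mean(lengths(test$items)),
    normalize = normalize
  ), class = "recall_score")
}

#' @export
print.recall_score <- function(x, ...) {
  cat(sprintf("<recall_score: global_error=%.4f, n_correct=%d/%d, mean_length=%.2f>\n",
              x$global_error, x$n_correct, nrow(x$items), x$mean_length))
  invisible(x)
}

#' Set-level learnability summaries
#'
#' Thin wrappers around [recall_score()]: `global_error()` is the mean
#' normalized edit distance between each test string and its closest training
#' item; `n_correct()` counts test items recalled symbol-for-symbol;
#' `mean_length()` is the mean item length of a single set.
#'
#' @param training,test Nonempty string sets.
#' @param normalize See [normalized_edit_distance()].
#' @return A single number.
#' @examples
#' global_error("ABCD", "ABCE") # 0.25
#' @export
global_error <- function(training, test, normalize = c("max", "path")) {
  recall_score(training, test, normalize)$global_error
}

#' @rdname global_error
#' @export
n_correct <- function(training, test) {
  training <- as_string_set(training)
  test <- as_string_set(test)
  if (length(training) == 0L || length(test) == 0L) {
    stop("training and test sets must be nonempty")
  }
  sum(as.character(test) %in% as.character(training))
}

#' @rdname global_error
#' @param s A nonempty string set.
#' @export
mean_length <- function(s) {
  s <- as_string_set(s)
  if (length(s) == 0L) stop("cannot take the mean length of an empty set")
  mean(lengths(s$items))
}
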