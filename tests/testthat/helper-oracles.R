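# Independent reference implementations used as oracles.

# Textbook Wagner-Fischer dynamic program, written against the recurrence
# directly and independent of the package's edit-distance path.
dp_levenshtein <- function(a, b) {
  a <- if (length(a) == 1L) strsplit(a, "")[[1L]] else a
  b <- if (length(b) == 1L) strsplit(b, "")[[1L]] else b
  m <- length(a); n <- length(b)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1L, j + 1L] <- min(D[i, j] + (a[i] != b[j]),
                               D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  D[m + 1L, n + 1L]
}

# Brute-force ACS: enumerate every contiguous substring of orders 2 and 3 by
# position, count its occurrences in the training strings by direct substring
# scanning, and average.
brute_acs <- function(test, training_strs) {
  subs <- function(x, k) {
    if (nchar(x) < k) return(character(0))
    vapply(seq_len(nchar(x) - k + 1L), function(i) substr(x, i, i + k - 1L),
           character(1))
  }
  frs <- c(subs(test, 2L), subs(test, 3L))
  count_in <- function(fr) {
    sum(vapply(training_strs, function(s) {
      k <- nchar(fr)
      if (nchar(s) < k) return(0L)
      sum(vapply(seq_len(nchar(s) - k + 1L),
                 function(i) substr(s, i, i + k - 1L) == fr, logical(1)))
    }, integer(1)))
  }
  mean(vapply(frs, count_in, numeric(1)))
}

# All strings of the given lengths over an alphabet, for exhaustive checks.
all_strings <- function(alphabet, lengths) {
  unlist(lapply(lengths, function(L) {
    if (L == 0L) return("")
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    apply(grid, 1L, paste, collapse = "")
  }), use.names = FALSE)
}

# Edge set of a reuse network as a canonical sorted string, for comparing
# topology across symbol remappings.
edge_key <- function(net, rename = identity) {
  el <- igraph::as_edgelist(net)
  if (!nrow(el)) return(character(0))
  a <- rename(el[, 1L]); b <- rename(el[, 2L])
  sort(paste(pmin(a, b), pmax(a, b)))
}
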