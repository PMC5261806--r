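#' Do two strings share a bigram?
#'
#' True iff the sets of contiguous bigrams of the two strings intersect; the
#' connection rule of the reuse network.
#'
#' @param a,b Symbol strings.
#' @return Logical scalar.
#' @examples
#' shares_bigram("215686", "83915") # TRUE, shared "15"
#' shares_bigram("1492", "123456")  # FALSE
#' @export
shares_bigram <- function(a, b) {
  a <- as_symbols(a)
  b <- as_symbols(b)
  sep <- if (any(nchar(c(a, b)) > 1L)) " " else ""
  length(intersect(ngrams(a, 2L, sep = sep), ngrams(b, 2L, sep = sep))) > 0L
}

#' Build a bigram-sharing reuse network
#'
#' Nodes are the unique string types of the set (duplicates collapse); two
#' nodes are connected by an undirected edge iff they share at least one
#' contiguous bigram. Strings of length 1 become isolated nodes. The
#' resulting graph carries per-node `length` attributes and graph-level
#' `provenance` (`"original"` or `"shuffled"`) and `source` labels.
#'
#' @param s A `string_set` (or coercible).
#' @param source Free-text label describing where the strings came from.
#' @param provenance `"original"` data or a `"shuffled"` null realization.
#' @return An [igraph][igraph::igraph-package] graph.
#' @examples
#' g <- build_reuse_network(c("ABC", "ABD", "XYZ"))
#' igraph::ecount(g) # 1
#' @export
build_reuse_network <- function(s, source = "stringset",
                                provenance = c("original", "shuffled")) {
  provenance <- match.arg(provenance)
  s <- as_string_set(s)
  strs <- as.character(s)
  keep <- !duplicated(strs)
  strs <- strs[keep]
  items <- s$items[keep]
  n <- length(strs)
  bigram_sets <- lapply(items, function(sym) unique(ngrams(sym, 2L, sep = s$sep)))
  # index strings by bigram; every pair within a bigram's member list is an edge
  incidence <- split(rep(seq_len(n), lengths(bigram_sets)),
                     unlist(bigram_sets, use.names = FALSE))
  pairs <- lapply(incidence, function(idx) {
    if (length(idx) < 2L) return(NULL)
    utils::combn(sort(idx), 2L)
  })
  pairs <- do.call(cbind, c(list(matrix(integer(0), nrow = 2L)), pairs))
  if (ncol(pairs)) {
    pairs <- unique(t(pairs))
  } else {
    pairs <- matrix(integer(0), ncol = 2L)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = strs)
  g <- igraph::set_vertex_attr(g, "length", value = lengths(items))
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  g <- igraph::set_graph_attr(g, "provenance", provenance)
  igraph::set_graph_attr(g, "source", source)
}

#' Per-node connectivity records of a reuse network
#'
#' For each node, the proportion of other strings in the set to which it is
#' connected: degree divided by (number of nodes - 1).
#'
#' @param net A reuse network from [build_reuse_network()].
#' @param replicate Optional integer identifying a shuffle replicate.
#' @return Data frame with columns `string`, `length`,
#'   `proportion_connected`, `condition`, `source`, `replicate`.
#' @export
connectivity_records <- function(net, replicate = NA_integer_) {
  n <- igraph::vcount(net)
  if (n < 2L) stop("connectivity is undefined for networks with fewer than 2 nodes")
  data.frame(
    string = igraph::vertex_attr(net, "name"),
    length = igraph::vertex_attr(net, "length"),
    proportion_connected = igraph::degree(net) / (n - 1L),
    condition = igraph::graph_attr(net, "provenance"),
    source = igraph::graph_attr(net, "source"),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Shuffle symbols within each string
#'
#' The within-string permutation null model: each string's symbols are
#' independently permuted, destroying sequential order while conserving every
#' string's length and symbol multiset (and hence the set-level symbol
#' counts).
#'
#' @param s A `string_set` (or coercible).
#' @param seed Optional integer seed.
#' @return A `string_set` of shuffled strings.
#' @export
shuffle_within_strings <- function(s, seed = NULL) {
  s <- as_string_set(s)
  if (!is.null(seed)) set.seed(seed)
  out <- s
  out$items <- lapply(s$items, function(sym) sym[sample.int(length(sym))])
  out
}

#' Connectivity-by-length scaling regression
#'
#' Ordinary least squares fit of `proportion_connected ~ length * condition`
#' over pooled original and shuffled connectivity records. The shuffled
#' condition is the reference level, so the `condition` coefficient is the
#' original-data connectivity advantage and the `length:condition`
#' interaction is the difference in connectivity-by-length slopes — the
#' signature of chunk reuse scaling with string length.
#'
#' @param records Data frame of [connectivity_records()] rows from both
#'   conditions.
#' @param cluster If `TRUE`, report cluster-robust standard errors clustered
#'   by string (via [sandwich::vcovCL()]); default is ordinary homoskedastic
#'   errors.
#' @return A `scaling_fit`: `$coefficients` (rows `intercept`, `length`,
#'   `condition`, `length_x_condition`; columns `estimate`, `se`, `t`, `p`),
#'   `$n`, and the underlying `$model`.
#' @export
scaling_fit <- function(records, cluster = FALSE) {
  req <- c("length", "proportion_connected", "condition")
  if (!all(req %in% names(records))) {
    stop("`records` must contain columns ", paste(req, collapse = ", "))
  }
  conds <- unique(records$condition)
  if (!all(conds %in% c("original", "shuffled"))) {
    stop("conditions must be 'original' and 'shuffled'")
  }
  if (length(conds) < 2L) {
    stop("condition term collapsed: only the '", conds, "' condition is present")
  }
  if (length(unique(records$length)) < 2L) {
    stop("length term collapsed: records contain a single string length")
  }
  records$condition <- factor(records$condition, levels = c("shuffled", "original"))
  fit <- lm(proportion_connected ~ length * condition, data = records)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design: term(s) collapsed: ", paste(bad, collapse = ", "))
  }
  vc <- if (cluster) sandwich::vcovCL(fit, cluster = records$string) else vcov(fit)
  est <- coef(fit)
  se <- sqrt(diag(vc))
  tval <- est / se
  df <- fit$df.residual
  tab <- data.frame(estimate = est, se = se, t = tval,
                    p = 2 * pt(abs(tval), df, lower.tail = FALSE))
  rownames(tab) <- c("intercept", "length", "condition", "length_x_condition")
  structure(list(coefficients = tab, n = nrow(records), df = df,
                 cluster = cluster, model = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit: n=%d, %s SEs>\n", x$n,
              if (x$cluster) "cluster-robust" else "OLS"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Original-versus-shuffled network comparison
#'
#' Builds the reuse network of a string set and of `n_shuffles` within-string
#' shuffled replicates, and pools their connectivity records for
#' [scaling_fit()]. Replicated shuffles (rather than the single shuffle of a
#' one-off baseline) smooth out realization noise; each replicate is tagged
#' in the `replicate` column.
#'
#' @param s A `string_set` (or coercible).
#' @param n_shuffles Number of shuffled replicates (>= 1).
#' @param seed Optional integer seed.
#' @param source Label propagated to the records.
#' @return A `shuffle_comparison`: `$records` (pooled connectivity records),
#'   `$mean_connectivity` (named by condition).
#' @export
shuffle_comparison <- function(s, n_shuffles = 100L, seed = NULL,
                               source = "stringset") {
  s <- as_string_set(s)
  if (!is.null(seed)) set.seed(seed)
  orig <- connectivity_records(build_reuse_network(s, source = source))
  reps <- lapply(seq_len(n_shuffles), function(r) {
    sh <- shuffle_within_strings(s)
    connectivity_records(
      build_reuse_network(sh, source = source, provenance = "shuffled"),
      replicate = r)
  })
  records <- rbind(orig, do.call(rbind, reps))
  means <- tapply(records$proportion_connected, records$condition, mean)
  structure(list(records = records,
                 mean_connectivity = means[c("original", "shuffled")],
                 n_shuffles = n_shuffles, source = source),
            class = "shuffle_comparison")
}

#' @export
print.shuffle_comparison <- function(x, ...) {
  cat(sprintf("<shuffle_comparison: %s, %d shuffles>\n", x$source, x$n_shuffles))
  cat(sprintf("  mean connectivity: original=%.4f shuffled=%.4f\n",
              x$mean_connectivity[["original"]], x$mean_connectivity[["shuffled"]]))
  invisible(x)
}

#' Similarity layout of a string set
#'
#' Embeds a string set in the plane for qualitative inspection: edges connect
#' bigram-sharing pairs, edge weight is the inverse edit distance
#' `1 / (1 + d)` (so identical strings would get the maximal weight and no
#' division by zero occurs), and coordinates come from the Kamada-Kawai
#' force-directed algorithm with desired edge lengths proportional to
#' `1 + d`. Strings using similar chunks therefore land close together.
#'
#' @param s A `string_set` (or coercible) with at least 2 items.
#' @param seed Optional integer seed (the embedding is deterministic given
#'   the seed).
#' @return A `similarity_layout`: `$coords` (data frame `string`, `x`, `y`)
#'   and `$edges` (data frame `from`, `to`, `weight`).
#' @export
similarity_layout <- function(s, seed = NULL) {
  s <- as_string_set(s)
  if (length(s) < 2L) stop("layout needs at least 2 strings")
  if (!is.null(seed)) set.seed(seed)
  g <- build_reuse_network(s)
  strs <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    idx_items <- s$items[!duplicated(as.character(s))]
    names(idx_items) <- strs
    d <- mapply(function(a, b) edit_distance(idx_items[[a]], idx_items[[b]]),
                el[, 1L], el[, 2L])
    w <- 1 / (1 + d)
    g <- igraph::set_edge_attr(g, "weight", value = 1 + d)
  } else {
    w <- numeric(0)
  }
  xy <- igraph::layout_with_kk(g, weights = if (nrow(el)) 1 + d else NULL)
  structure(list(
    coords = data.frame(string = strs, x = xy[, 1L], y = xy[, 2L],
                        stringsAsFactors = FALSE),
    edges = data.frame(from = el[, 1L], to = el[, 2L], weight = w,
                       stringsAsFactors = FALSE)
  ), class = "similarity_layout")
}

#' @export
plot.similarity_layout <- function(x, ...) {
  co <- x$coords
  plot(co$x, co$y, type = "n", axes = FALSE, xlab = "", ylab = "", ...)
  if (nrow(x$edges)) {
    i <- match(x$edges$from, co$string)
    j <- match(x$edges$to, co$string)
    segments(co$x[i], co$y[i], co$x[j], co$y[j],
             lwd = 0.5 + 4 * x$edges$weight, col = "grey70")
  }
  text(co$x, co$y, co$string, cex = 0.8)
  invisible(x)
}
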