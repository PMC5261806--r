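#' Per-generation metrics of a chain
#'
#' For each transmission step `g-1 -> g` of a chain, computes the four core
#' measures: global error (mean normalized edit distance to the closest
#' training item), number of exactly recalled items, mean string length of
#' the recalled set, and global Associative Chunk Strength of the recalled
#' set against the previous generation.
#'
#' @param x A [chain()].
#' @param mode ACS normalization mode, see [fragment_table()].
#' @param normalize Edit-distance normalization, see
#'   [normalized_edit_distance()].
#' @return Data frame with columns `chain`, `generation` (1..G),
#'   `global_error`, `n_correct`, `mean_length`, `acs_global`.
#' @export
chain_metrics <- function(x, mode = "per_item_norm", normalize = "max") {
  stopifnot(inherits(x, "chain"))
  G <- n_generations(x)
  rows <- lapply(seq_len(G), function(g) {
    training <- generation(x, g - 1L)
    test <- generation(x, g)
    sc <- recall_score(training, test, normalize = normalize)
    data.frame(
      chain = if (!is.null(x$chain_id)) as.character(x$chain_id) else NA_character_,
      generation = g,
      global_error = sc$global_error,
      n_correct = sc$n_correct,
      mean_length = sc$mean_length,
      acs_global = acs_global(training, test, mode = mode, on_short = "zero"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Aggregate report over a set of chains
#'
#' Assembles the chain-level analysis: per-generation metrics for every
#' chain, across-chain means with standard errors of the mean, a
#' first-versus-last [paired_t()] and a cross-generation [trend_test()] for
#' each measure. Accepts chain objects or chain directories on disk.
#'
#' @param chains A `chain`, a list of chains, or a character vector of chain
#'   directory paths (each readable by [read_chain()]).
#' @param mode,normalize Passed to [chain_metrics()].
#' @param first,last Generations compared by the paired tests; defaults to
#'   the first (1) and last recalled generation.
#' @param out_dir Optional directory; if given, `metrics.csv`,
#'   `summary.csv`, `tests.csv` and a JSON run manifest are written there.
#'   Outputs are byte-identical across re-runs on the same inputs.
#' @return A `chain_report`: `$metrics` (per chain x generation),
#'   `$summary` (per generation x measure: mean, sem, n_chains), `$tests`
#'   (per measure: paired t and trend test results; `NULL` with fewer than 2
#'   chains).
#' @export
run_report <- function(chains, mode = "per_item_norm", normalize = "max",
                       first = 1L, last = NULL, out_dir = NULL) {
  if (inherits(chains, "chain")) chains <- list(chains)
  if (is.character(chains)) chains <- lapply(chains, read_chain)
  if (!length(chains) || !all(vapply(chains, inherits, logical(1), "chain"))) {
    stop("`chains` must be chains or chain directory paths")
  }
  for (i in seq_along(chains)) {
    if (is.null(chains[[i]]$chain_id)) chains[[i]]$chain_id <- as.character(i)
  }
  G <- unique(vapply(chains, n_generations, integer(1)))
  if (length(G) != 1L) stop("all chains must have the same number of generations")
  if (is.null(last)) last <- G
  if (first < 1L || last > G || first >= last) {
    stop("`first` and `last` must satisfy 1 <= first < last <= ", G)
  }
  metrics <- do.call(rbind, lapply(chains, chain_metrics,
                                   mode = mode, normalize = normalize))
  measures <- c("global_error", "n_correct", "mean_length", "acs_global")
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(generation = metrics$generation, measure = m,
               value = metrics[[m]], stringsAsFactors = FALSE)
  }))
  summary <- aggregate(value ~ measure + generation, data = long,
                       FUN = function(v) c(mean = mean(v),
                                           sem = sd(v) / sqrt(length(v)),
                                           n = length(v)))
  summary <- data.frame(summary[c("measure", "generation")],
                        mean = summary$value[, "mean"],
                        sem = summary$value[, "sem"],
                        n_chains = as.integer(summary$value[, "n"]),
                        stringsAsFactors = FALSE)
  summary <- summary[order(summary$measure, summary$generation), ]
  rownames(summary) <- NULL

  tests <- NULL
  if (length(chains) >= 2L) {
    tests <- do.call(rbind, lapply(measures, function(m) {
      v_first <- metrics[[m]][metrics$generation == first]
      v_last <- metrics[[m]][metrics$generation == last]
      pt_res <- tryCatch(paired_t(v_first, v_last), error = function(e) NULL)
      tr <- tryCatch(
        trend_test(data.frame(chain = metrics$chain,
                              generation = metrics$generation,
                              value = metrics[[m]])),
        error = function(e) NULL)
      data.frame(
        measure = m,
        comparison = c(sprintf("generation %d vs %d", first, last), "trend"),
        t = c(if (is.null(pt_res)) NA_real_ else pt_res$t,
              if (is.null(tr)) NA_real_ else tr$t),
        df = c(if (is.null(pt_res)) NA_real_ else pt_res$df,
               if (is.null(tr)) NA_real_ else tr$df),
        p = c(if (is.null(pt_res)) NA_real_ else pt_res$p,
              if (is.null(tr)) NA_real_ else tr$p),
        method = c("paired_t", "chain_slopes"),
        stringsAsFactors = FALSE
      )
    }))
    rownames(tests) <- NULL
  }

  out <- structure(list(metrics = metrics, summary = summary, tests = tests,
                        first = first, last = last, mode = mode,
                        normalize = normalize),
                   class = "chain_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(tests)) {
      utils::write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
    }
    manifest <- list(
      command = "run_report",
      n_chains = length(chains),
      n_generations = G,
      mode = mode, normalize = normalize,
      first = first, last = last,
      outputs = c("metrics.csv", "summary.csv",
                  if (!is.null(tests)) "tests.csv"),
      package_version = as.character(utils::packageVersion("seqchains"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' @export
print.chain_report <- function(x, ...) {
  n_ch <- length(unique(x$metrics$chain))
  cat(sprintf("<chain_report: %d chain(s), generations 1..%d>\n",
              n_ch, max(x$metrics$generation)))
  cat("Across-chain means (first and last generation):\n")
  s <- x$summary[x$summary$generation %in% c(1L, max(x$summary$generation)), ]
  print(transform(s, mean = round(mean, 4), sem = round(sem, 4)), row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("Tests:\n")
    print(transform(x$tests, t = round(t, 3), p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}
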