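#' Paired t-test over chains
#'
#' Classical paired-samples t-test of per-chain values at two time points
#' (e.g. global error at the first versus last generation of each chain),
#' with `df = n - 1`. The statistic is computed on the differences `y - x`,
#' so a positive `t` means `y` exceeds `x`.
#'
#' @param x,y Numeric vectors of equal length >= 2, one value per chain.
#' @return A `paired_t_result`: `$t`, `$df`, `$p` (two-sided),
#'   `$mean_diff`, `$means`, `$sds`, `$n`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5)) # t = 4, df = 2
#' @export
paired_t <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("`x` and `y` must be numeric")
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("the paired test needs at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values in paired data")
  d <- y - x
  if (sd(d) == 0) {
    stop("degenerate paired test: the differences have zero variance")
  }
  tt <- t.test(d, mu = 0)
  structure(list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    mean_diff = mean(d),
    means = c(x = mean(x), y = mean(y)),
    sds = c(x = sd(x), y = sd(y)),
    n = length(x)
  ), class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%d) = %.3f, p = %.4g, mean difference = %.4f\n",
              x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' Cross-generation trend test
#'
#' Tests whether a per-generation measure trends across generations,
#' accounting for chain as the sampling unit: an ordinary-least-squares slope
#' of the measure on generation index is fit within each chain, and the
#' slopes are tested against zero with a one-sample t-test
#' (`df = n_chains - 1`). This is the conservative, exactly specified
#' equivalent of a mixed-model trend with random slopes by chain.
#'
#' @param series Either a numeric matrix (rows = chains, columns =
#'   generations in order) or a data frame with columns `chain`,
#'   `generation`, `value`.
#' @return A `trend_result`: `$slopes` (one per chain), `$mean_slope`, `$t`,
#'   `$df`, `$p`, `$method`.
#' @export
trend_test <- function(series) {
  if (is.matrix(series)) {
    gens <- if (!is.null(colnames(series))) as.numeric(colnames(series))
            else seq_len(ncol(series))
    series <- data.frame(
      chain = rep(seq_len(nrow(series)), times = ncol(series)),
      generation = rep(gens, each = nrow(series)),
      value = as.vector(series)
    )
  }
  req <- c("chain", "generation", "value")
  if (!all(req %in% names(series))) {
    stop("`series` must have columns ", paste(req, collapse = ", "))
  }
  chains <- split(series, series$chain)
  if (length(chains) < 2L) stop("the trend test needs at least 2 chains")
  slopes <- vapply(names(chains), function(id) {
    d <- chains[[id]]
    if (length(unique(d$generation)) < 2L) {
      stop("chain '", id, "' has fewer than 2 distinct generation indices")
    }
    unname(coef(lm(value ~ generation, data = d))[2L])
  }, numeric(1))
  if (sd(slopes) == 0) {
    stop("degenerate trend test: per-chain slopes have zero variance")
  }
  tt <- t.test(slopes, mu = 0)
  structure(list(
    slopes = slopes,
    mean_slope = mean(slopes),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    method = "chain_slopes"
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend test (%s): mean slope = %.4f, t(%d) = %.3f, p = %.4g\n",
              x$method, x$mean_slope, x$df, x$t, x$p))
  invisible(x)
}
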