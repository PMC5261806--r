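#' Configuration of the chunk-based learner model
#'
#' Parameters of the simulated learner used by [simulate_chain()]. The model
#' is deliberately simple: it exists to generate chains carrying the
#' statistical signatures the analysis pipeline is designed to detect
#' (falling recall error, rising chunk reuse, stable lengths), not to model
#' human memory.
#'
#' @param n_blocks Training exposures per generation: every training item is
#'   seen this many times, multiplying the fragment counts the learner
#'   accumulates. Default 6, the number of training blocks in the recall
#'   procedure.
#' @param reuse_bias Chunk-sampling exponent `gamma >= 0`: during
#'   reconstruction, bigrams are sampled with probability proportional to
#'   `frequency^gamma`. 0 ignores frequency entirely; larger values
#'   concentrate reuse on frequent chunks. Default 1.5.
#' @param verbatim_gain Length-2 numeric `(a, b)`: an item is reproduced
#'   verbatim with probability `plogis(a + b * ACS_item)`, where `ACS_item`
#'   is the item's Associative Chunk Strength against the exposure-weighted
#'   per-item-normalized fragment table. High-chunk-strength items are thus
#'   recalled more reliably. Default `c(-1, 2)`.
#' @param symbol_noise Per-symbol substitution probability `epsilon` in
#'   `[0, 1]` applied to reconstructed strings. Default 0.05.
#' @param max_unique_attempts Resampling budget per item for satisfying the
#'   all-outputs-unique requirement before forced perturbation. Default 100.
#' @param overlap_mode How sampled bigrams are concatenated during
#'   reconstruction: `"chain"` links bigrams tail-to-head (overlapping one
#'   symbol) where possible, falling back to juxtaposition; `"juxtapose"`
#'   never overlaps.
#' @return A `learner_config`.
#' @export
learner_config <- function(n_blocks = 6L, reuse_bias = 1.5,
                           verbatim_gain = c(-1, 2), symbol_noise = 0.05,
                           max_unique_attempts = 100L,
                           overlap_mode = c("chain", "juxtapose")) {
  overlap_mode <- match.arg(overlap_mode)
  if (!is_whole_number(n_blocks) || n_blocks < 1) stop("`n_blocks` must be a positive integer")
  if (!is.numeric(reuse_bias) || length(reuse_bias) != 1L || reuse_bias < 0) {
    stop("`reuse_bias` must be a single number >= 0")
  }
  if (!is.numeric(verbatim_gain) || length(verbatim_gain) != 2L || anyNA(verbatim_gain)) {
    stop("`verbatim_gain` must be numeric of length 2 (may include -Inf)")
  }
  if (!is.numeric(symbol_noise) || length(symbol_noise) != 1L ||
      symbol_noise < 0 || symbol_noise > 1) {
    stop("`symbol_noise` must be a probability in [0, 1]")
  }
  if (!is_whole_number(max_unique_attempts) || max_unique_attempts < 1) {
    stop("`max_unique_attempts` must be a positive integer")
  }
  structure(list(n_blocks = as.integer(n_blocks), reuse_bias = reuse_bias,
                 verbatim_gain = verbatim_gain, symbol_noise = symbol_noise,
                 max_unique_attempts = as.integer(max_unique_attempts),
                 overlap_mode = overlap_mode),
            class = "learner_config")
}

#' @export
print.learner_config <- function(x, ...) {
  cat(sprintf(paste0("<learner_config: n_blocks=%d, reuse_bias=%.2f, ",
                     "verbatim_gain=(%g, %g), symbol_noise=%.3f, %s>\n"),
              x$n_blocks, x$reuse_bias, x$verbatim_gain[1], x$verbatim_gain[2],
              x$symbol_noise, x$overlap_mode))
  invisible(x)
}

# One simulated recall pass: training set in, recalled set of unique items out.
recall_generation <- function(training, cfg) {
  items <- training$items
  alpha <- training$alphabet
  n <- length(items)
  ft <- fragment_table(training, mode = "per_item_norm", exposures = cfg$n_blocks)
  raw_bi <- fragment_table(training, mode = "raw_count", n = 2L)$counts
  bi_syms <- if (training$sep == " ") strsplit(names(raw_bi), " ", fixed = TRUE)
             else strsplit(names(raw_bi), "", fixed = TRUE)
  bw <- raw_bi^cfg$reuse_bias
  heads <- vapply(bi_syms, `[`, character(1), 1L)
  lens <- lengths(items)

  reconstruct <- function() {
    L <- sample_one(lens)
    if (!length(bw)) {
      sym <- sample(alpha, L, replace = TRUE)
    } else {
      k <- sample.int(length(bw), 1L, prob = bw)
      sym <- bi_syms[[k]]
      while (length(sym) < L) {
        cont <- which(heads == sym[length(sym)])
        if (cfg$overlap_mode == "chain" && length(cont)) {
          k <- cont[sample.int(length(cont), 1L, prob = bw[cont])]
          sym <- c(sym, bi_syms[[k]][2L])
        } else {
          k <- sample.int(length(bw), 1L, prob = bw)
          sym <- c(sym, bi_syms[[k]])
        }
      }
      sym <- sym[seq_len(L)]
    }
    if (cfg$symbol_noise > 0) {
      flip <- runif(L) < cfg$symbol_noise
      if (any(flip)) {
        sym[flip] <- vapply(sym[flip], function(cur) {
          sample_one(setdiff(alpha, cur))
        }, character(1))
      }
    }
    sym
  }

  produced <- character(0)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    acs <- acs_item(items[[i]], ft, on_short = "zero")
    p_verb <- plogis(cfg$verbatim_gain[1L] + cfg$verbatim_gain[2L] * acs)
    cand <- NULL
    for (att in seq_len(cfg$max_unique_attempts)) {
      cand <- if (runif(1) < p_verb) items[[i]] else reconstruct()
      if (!(collapse_symbols(cand, training$sep) %in% produced)) break
      cand <- NULL
    }
    if (is.null(cand)) {
      # forced perturbation mirrors the experiment's retype-until-unique rule
      cand <- reconstruct()
      for (att in seq_len(1000L)) {
        pos <- sample.int(length(cand), 1L)
        cand[pos] <- sample_one(setdiff(alpha, cand[pos]))
        if (!(collapse_symbols(cand, training$sep) %in% produced)) break
        if (att == 1000L) stop("could not produce a unique string after forced perturbation")
      }
    }
    produced <- c(produced, collapse_symbols(cand, training$sep))
    out[[i]] <- cand
  }
  string_set(out, alphabet = alpha, kind = training$kind)
}

#' Simulate an iterated-learning chain
#'
#' Runs the chunk-based learner of [learner_config()] for `n_generations`
#' transmission steps: each generation trains on the previous generation's
#' output, reproduces each item verbatim with a probability increasing in
#' the item's Associative Chunk Strength, and otherwise reconstructs a
#' string of a training-set length by chaining frequency-weighted bigrams,
#' with per-symbol substitution noise. Outputs are forced to be 15 unique
#' strings, mirroring the experimental recall requirement.
#'
#' @param initial The generation-0 `string_set`.
#' @param config A [learner_config()].
#' @param n_generations Number of transmission steps (>= 1); default 10.
#' @param seed Optional integer seed; the full chain is deterministic given
#'   the seed.
#' @param chain_id Optional identifier stored on the chain.
#' @param validate `"basic"` (default) requires unique items; `"full"`
#'   additionally requires the initial set to pass [validate_initial_set()];
#'   `"none"` skips checks.
#' @return A [chain()] with `n_generations + 1` string sets.
#' @examples
#' ch <- simulate_chain(initial_string_set(1), n_generations = 3, seed = 42)
#' n_generations(ch)
#' @export
simulate_chain <- function(initial, config = learner_config(),
                           n_generations = 10L, seed = NULL, chain_id = NULL,
                           validate = c("basic", "full", "none")) {
  validate <- match.arg(validate)
  initial <- as_string_set(initial, kind = "experiment")
  if (!inherits(config, "learner_config")) stop("`config` must be a learner_config")
  if (!is_whole_number(n_generations) || n_generations < 1) {
    stop("`n_generations` must be a positive integer")
  }
  if (validate == "basic" && anyDuplicated(as.character(initial))) {
    stop("the initial set must contain unique strings")
  }
  if (validate == "full" && !validate_initial_set(initial)$passes) {
    stop("the initial set fails full generation-0 validation")
  }
  if (!is.null(seed)) set.seed(seed)
  gens <- vector("list", n_generations + 1L)
  gens[[1L]] <- initial
  for (g in seq_len(n_generations)) {
    gens[[g + 1L]] <- recall_generation(gens[[g]], config)
  }
  chain(gens, chain_id = chain_id)
}

#' Configuration of the synthetic part-of-speech corpus generator
#'
#' A first-order Markov chain over a small part-of-speech tag inventory,
#' standing in for sentence material reduced to tag sequences. The default
#' inventory has the 15 tags used for child-directed speech: noun, verb,
#' adjective, adverb, determiner, preposition, negation, conjunction,
#' pronoun, relativizer, quantifier, onomatopoeia, interjection, infinitival
#' and neologism.
#'
#' @param tags Character vector of tag symbols.
#' @param transition Row-stochastic transition matrix (`length(tags)` square,
#'   rows summing to 1 within 1e-9). Default: uniform transitions (no
#'   sequential structure); see [random_transition_matrix()] for structured
#'   alternatives.
#' @param lengths Sequence lengths to draw uniformly from (default 3:6).
#' @param n Number of sequences to generate (default 500).
#' @return A `pos_grammar_config`.
#' @export
pos_grammar_config <- function(tags = c("noun", "verb", "adjective", "adverb",
                                        "determiner", "preposition", "negation",
                                        "conjunction", "pronoun", "relativizer",
                                        "quantifier", "onomatopoeia",
                                        "interjection", "infinitival", "neologism"),
                               transition = NULL, lengths = 3:6, n = 500L) {
  tags <- as.character(tags)
  if (length(tags) < 2L || anyDuplicated(tags)) stop("`tags` must be >= 2 distinct symbols")
  k <- length(tags)
  if (is.null(transition)) {
    transition <- matrix(1 / k, k, k, dimnames = list(tags, tags))
  }
  if (!is.matrix(transition) || nrow(transition) != k || ncol(transition) != k) {
    stop("`transition` must be a ", k, " x ", k, " matrix")
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must be non-negative and sum to 1 (tolerance 1e-9)")
  }
  dimnames(transition) <- list(tags, tags)
  if (!is_whole_number(n) || n < 1) stop("`n` must be a positive integer")
  structure(list(tags = tags, transition = transition,
                 lengths = lengths, n = as.integer(n)),
            class = "pos_grammar_config")
}

#' Random row-stochastic transition matrix
#'
#' Draws each row from a symmetric Dirichlet distribution. Small
#' `concentration` values give sparse, strongly structured transitions (a
#' few high-probability continuations per tag); large values approach
#' uniform transitions.
#'
#' @param k Number of states.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Optional integer seed.
#' @return A `k` x `k` row-stochastic matrix.
#' @export
random_transition_matrix <- function(k, concentration = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("`concentration` must be positive")
  }
  m <- matrix(stats::rgamma(k * k, shape = concentration), k, k)
  m / rowSums(m)
}

#' Generate a synthetic part-of-speech sequence corpus
#'
#' Samples tag sequences from the first-order chain of a
#' [pos_grammar_config()]: the first tag from the chain's stationary
#' distribution (computed by power iteration from a uniform start), each
#' following tag from the transition row of its predecessor, sequence
#' lengths uniform over the configured range.
#'
#' @param config A `pos_grammar_config`.
#' @param seed Optional integer seed.
#' @return A `string_set` of kind `"generic"` whose symbols are tag tokens.
#' @export
generate_pos_corpus <- function(config = pos_grammar_config(), seed = NULL) {
  if (!inherits(config, "pos_grammar_config")) {
    stop("`config` must be a pos_grammar_config")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(config$tags)
  start <- rep(1 / k, k)
  for (i in seq_len(200L)) start <- as.vector(start %*% config$transition)
  items <- lapply(seq_len(config$n), function(i) {
    L <- sample_one(config$lengths)
    idx <- integer(L)
    idx[1L] <- sample.int(k, 1L, prob = start)
    for (j in seq_len(L - 1L)) {
      idx[j + 1L] <- sample.int(k, 1L, prob = config$transition[idx[j], ])
    }
    config$tags[idx]
  })
  string_set(items, alphabet = config$tags, kind = "generic")
}

#' Generate a random digit stream
#'
#' Independent uniform draws over the digit alphabet, standing in for the
#' concatenated output of a random-number generation task.
#'
#' @param n Stream length (>= 1).
#' @param seed Optional integer seed.
#' @param alphabet `"digits"` for 0-9 single characters, `"one_to_ten"` for
#'   the numbers 1-10 as whole-number tokens (so "10" is one symbol and
#'   contributes no internal bigram).
#' @return A [digit_stream()].
#' @export
random_digit_stream <- function(n, seed = NULL,
                                alphabet = c("digits", "one_to_ten")) {
  alphabet <- match.arg(alphabet)
  if (!is_whole_number(n) || n < 1) stop("`n` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  syms <- switch(alphabet, digits = as.character(0:9),
                 one_to_ten = as.character(1:10))
  digit_stream(sample(syms, n, replace = TRUE),
               provenance = paste0("random_", alphabet))
}
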