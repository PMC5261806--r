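---
title: "Analysing sequence memory chains: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sequence memory chains: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqchains)
```

## The problem

In an iterated-learning (diffusion-chain) recall experiment, a learner is
trained on a set of 15 nonsense consonant strings and then asked to recall
them; the recalled set becomes the training material for the next learner,
for ten "generations" per chain. Because human sequence memory is severely
limited, whatever structure makes string sets easier to recall tends to
accumulate over generations. The analyses in this package quantify that
accumulation along three axes: learnability (recall fidelity), distributional
structure (chunk reuse), and network structure (how densely strings are
interconnected by shared bigrams, compared against shuffle null models and
generic digit-sequence baselines).

## Seed sets and their constraints

A generation-0 set contains 15 unique strings — five each of lengths 3, 4 and
5 — over an alphabet of exactly 6 consonants, each appearing 10 times (60
symbols in total). To leave no sequential structure at the outset, fragment
frequencies are capped: no bigram may occur more than 3 times and no trigram
more than 2 times across the whole set.

`validate_initial_set()` checks all of these. Two interpretive choices are
worth stating:

* **Repetition caps count tokens, pooled across the set.** The caps exist to
  keep fragment frequencies near-uniform *throughout the string set*, which
  is a property of pooled token counts of contiguous within-string n-grams,
  not of per-string or type counts. All eight shipped seed sets respect the
  caps under this reading.
* **Letter-count uniformity is checked exactly** (each symbol exactly 10
  times). Two of the eight shipped seed sets, as published, have one letter
  at 9 and another at 11 occurrences; `validate_initial_set()` reports them
  as failing the `symbol_uniformity` check while passing everything else. The
  fixtures are shipped exactly as published rather than silently corrected.

`generate_initial_set()` produces fresh seed sets by rejection sampling:
shuffle the 60-symbol multiset into the fifteen length slots and accept iff
the candidate validates. This is unbiased over the constraint-satisfying
space and typically accepts within a handful of attempts, so the default
restart cap (100,000) is effectively never reached.

Symbols are case-normalized to uppercase on ingest. The acronym screening
applied by human experimenters between sessions is approximated by an
optional word-list filter in `remap_symbols()`/`random_remap()` (off by
default): a remapping is rejected if any remapped string matches a supplied
word list. Human judgment of "looks like an acronym" is not implementable;
the filter is a mechanical stand-in.

## Learnability scoring

Recall fidelity between consecutive generations is scored per item: each
recalled string is matched to the training item minimizing the Levenshtein
distance (unit-cost insertions, deletions, substitutions), and the error is
that distance normalized to [0, 1]. Two normalizations are available:

* `"max"` (default): distance divided by the longer of the two strings. It is
  bounded, symmetric, and reduces to the raw edit count on equal-length
  worked examples.
* `"path"`: the Marzal–Vidal path-normalized distance (minimum over edit
  paths of weight/length), for users who prefer a normalization with metric
  properties. On the short strings of this task the two orderings rarely
  disagree.

Ties in the closest-item search are broken toward the lexicographically
smallest training item; the tie-break affects only the reported partner,
never the score. Matching is deliberately independent per test item — one
training item may be the closest neighbour of several recalled strings — as
a bipartite assignment would presume a correspondence the recall task does
not provide. The set-level summaries are `global_error()` (mean normalized
error), `n_correct()` (exact matches) and `mean_length()`.

## Associative Chunk Strength

ACS measures how much a test string reuses the training set's chunks: the
mean training frequency of its contiguous bigrams and trigrams (a string
with `x` bigrams has `x − 1` trigrams; for ZVX, the frequencies of ZV, VX
and ZVX divided by 3). `fragment_table()` supports three frequency modes:

* `raw_count` — pooled token counts;
* `per_item_norm` — token counts divided by the number of training items
  (**default**);
* `presence_prop` — proportion of training items containing the fragment.

The default is `per_item_norm` because set-level ACS values under raw token
counts are incompatible with small published group means whenever several
items are recalled verbatim (each verbatim item alone contributes at least 1
to its own raw-count ACS); dividing by the number of training items yields
values on the scale such means are reported on. All three modes are exposed,
and every ACS function accepts the mode explicitly, so analyses against
externally deposited chain data can be run under each mode to determine
which one reproduces them. Length-2 strings have one fragment (divisor 1);
ACS of a length-1 string is undefined and errors by default
(`on_short = "zero"` opts into a 0 instead, which the simulator uses).

## Reuse networks and nulls

`build_reuse_network()` connects two strings iff they share at least one
contiguous bigram. Nodes are unique string types — experiment sets are
unique by construction, and generic collections (tag sequences, digit
strings) are type inventories. Connectivity of a node is its degree divided
by (n − 1).

The null model (`shuffle_within_strings()`) permutes symbols within each
string, destroying order while conserving each string's symbol multiset.
`shuffle_comparison()` defaults to 100 shuffle replicates, pooled into the
regression with a replicate identifier, rather than the single shuffle a
one-off baseline would use: a single realization of a 15-string null is
noisy, and replication changes only the precision, not the expectation, of
the baseline. Single-shuffle behaviour is available by setting
`n_shuffles = 1`.

`scaling_fit()` regresses connectivity on `length * condition` by ordinary
least squares with the shuffled condition as reference, so the `condition`
coefficient is the original-data connectivity advantage and the interaction
is the difference in connectivity-by-length slopes — the signature of chunk
reuse scaling with length. Homoskedastic standard errors are the default;
`cluster = TRUE` clusters by string for users worried about the same string
appearing under both conditions and across replicates. Pooling across
generations (e.g. the final three of a chain) versus fitting per generation
is left to the caller: `connectivity_records()` output from any collection
of networks can be concatenated before fitting.

On the eight seed sets the *shuffled* baseline is more connected than the
original data — unstructured sets lose nothing by shuffling, while the
length-stratified construction slightly disperses bigrams — and the
direction reverses in evolved or structured material. The package's tests
check exactly this reversal.

## Comparison-sequence baselines

Three generic sources feed the same network machinery unchanged:
`digit_string()` (frequency counts as digit sequences),
`password_digit_runs()` (maximal contiguous digit runs; the extraction rule
is unstated in the source literature, and maximal runs are the natural
parse — length-1 runs are kept and simply become isolated nodes), and
`sample_windows()` over a `digit_stream()` (windows of length 3–6, uniform
lengths and start positions, overlap permitted since the resampling is
explicitly repeated many times). The 1–10 random-number task is handled in
token mode: "10" is a single symbol, so no spurious bigram arises inside it.

## Inferential statistics

`paired_t()` is the classical paired t-test over chains (df = chains − 1),
used for first-versus-last comparisons. `trend_test()` fits an OLS slope of
the measure on generation within each chain and tests the slopes against
zero with a one-sample t-test. This per-chain-slope test replaces maximal
random-effects mixed models: it is exactly specified, dependency-free, and
conservative for eight chains, at the cost of not pooling information across
chains. Both tests refuse to fabricate statistics from degenerate input
(zero-variance differences or slopes raise errors). Generations 1 and 10 are
the default "initial" and "final" endpoints, configurable in `run_report()`.

## The chain simulator

`simulate_chain()` is this package's stand-in for human transmission chains.
It is **not** a cognitive model; it exists so that every pipeline stage has
inputs carrying the statistical signatures the analyses are designed to
detect, with a mechanism (chunk reuse under memory constraints) that can be
switched off to verify discriminant validity.

Per generation, the learner:

1. builds a fragment table from the training set, weighted by `n_blocks`
   exposures (default 6, the number of training blocks per session);
2. reproduces each item verbatim with probability
   `plogis(a + b · ACS_item)` (default `(a, b) = (−1, 2)`), so
   high-chunk-strength items survive transmission;
3. otherwise reconstructs a string: a length drawn from the training length
   distribution, built by sampling bigrams with probability proportional to
   `frequency^γ` (default γ = 1.5) and chaining them tail-to-head where
   possible (`overlap_mode = "chain"`; pure juxtaposition is available),
   then applying per-symbol substitution noise ε (default 0.05);
4. enforces 15 unique outputs, resampling up to `max_unique_attempts` and
   then perturbing single symbols — mirroring the experimental rule that
   every produced string be unique.

The defaults produce, over 10 generations, falling global error and rising
ACS with stable mean lengths, and final-generation networks whose original
connectivity exceeds the shuffled baseline. The ablated configuration
(`reuse_bias = 0`, `verbatim_gain = c(-Inf, 0)`, `symbol_noise = 1`) removes
the chunk mechanism and flattens the ACS trend to zero, which is the
simulator's discriminant check. What passing simulator-based tests show is
that the *pipeline* detects these signatures when present and not when
absent; they say nothing about human parameter values, and the simulator's
quantitative levels (e.g. its generation-1 error is lower than a human
learner's) are not calibrated to human data.

`generate_pos_corpus()` plays the analogous role for natural-language-like
material: a first-order Markov chain over a 15-tag part-of-speech inventory,
initial tag from the stationary distribution, lengths 3–6. Structured
transition matrices (`random_transition_matrix()` with small concentration)
yield corpora whose original networks out-connect their shuffled baselines;
uniform transitions do not. It emulates only first-order sequential
statistics — no grammar, no utterance-frequency weighting — so conclusions
about real child-directed speech require the real corpus.

## Problem sizes and numerics

The test suite and the acceptance script run everything at the study's own
design sizes: 8 chains × 10 generations × 15 strings, 100 shuffle replicates
per generation-0 null, 20 seeds for simulator and digit-null replications,
100 null simulations for the trend test's type-I calibration. All
randomness flows through explicit integer seeds; the same seed reproduces a
chain, a shuffle, a layout or a report byte-for-byte. Transition-matrix row
sums are checked to 1e−9; edit distances are exact integers; no smoothing is
applied to fragment frequencies (an absent fragment scores 0).

## Known limitations

* The learner model is a data generator, not a theory of memory; its
  parameters are conventions, not estimates.
* ACS is limited to bigrams and trigrams, as in the artificial-grammar
  tradition it comes from; higher-order reuse is invisible to it.
* The per-chain-slope trend test does not reproduce mixed-model p-values,
  only their qualitative conclusions.
* Published group means from the human experiment are reproducible only
  against the experiment's deposited chain data, which this package does not
  ship; the analysis entry points accept such data in the documented chain
  directory format.
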