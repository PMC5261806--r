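# seqchains

Analysis of iterated-learning ("diffusion chain") sequence memory
experiments, for cognitive scientists studying the cultural evolution of
sequence structure. In such experiments a learner is trained on a set of 15
nonsense consonant strings and asked to recall them; the recalled set trains
the next learner, for ten generations per chain. `seqchains` implements the
complete analysis pipeline around this design:

* **Stimulus construction** — constrained generation and validation of
  generation-0 string sets (15 unique strings, 5 each of lengths 3/4/5, 6
  consonants × 10 occurrences, bigram/trigram repetition caps 3/2), plus the
  eight published seed sets as fixtures, symbol remapping and length
  filtering.
* **Learnability** — per-item Levenshtein distance to the *closest* training
  item; global error `mean(d / max(|test|, |closest|))`, exact-recall counts
  and mean lengths (a Marzal–Vidal path-normalized distance is available).
* **Associative Chunk Strength (ACS)** — for a test string with `x` bigrams
  and `x − 1` trigrams, the mean training-set frequency of those fragments,
  e.g. `ACS(ZVX) = (f(ZV) + f(VX) + f(ZVX)) / 3`; three frequency
  normalizations, default counts per training item.
* **Reuse networks** — strings connected iff they share a contiguous bigram;
  connectivity `degree / (n − 1)`; within-string shuffle null models; the
  OLS scaling regression `connectivity ~ length × condition`; Kamada–Kawai
  similarity layouts with inverse-edit-distance edge weights.
* **Comparison baselines** — word frequencies as digit strings, maximal
  digit runs from passwords, and windows resampled from a digit stream, all
  feeding the same network machinery.
* **Inference** — first-vs-last paired t-tests and per-chain-slope trend
  tests across generations.
* **Simulation** — a chunk-based learner (`simulate_chain()`) whose chains
  show the qualitative signatures of the human data (falling error, rising
  ACS, stable lengths, densifying networks), a synthetic part-of-speech
  corpus generator and random digit streams.

## Worked example

```r
library(seqchains)

s0 <- initial_string_set(1)
s0
#> <string_set: 15 items, alphabet {C,F,L,M,P,S}, kind=experiment>
#>   CMC, SFL, PCS, LFF, FSM, MSMF, CLMP, PPSL, FLCM, SCPC, CSPLL, LFPSS, PFMLM, MLCFP, SPMCF
validate_initial_set(s0)$passes
#> [1] TRUE

ch <- simulate_chain(s0, n_generations = 10, seed = 101, chain_id = "demo")
recall_score(generation(ch, 0), generation(ch, 1))
#> <recall_score: global_error=0.2156, n_correct=8/15, mean_length=4.20>
```

The first simulated learner reproduced 8 of 15 strings exactly, and its
recalled strings sit on average 0.22 normalized edits away from their
closest training items. Aggregating eight chains reproduces the study-level
analysis:

```r
chains <- lapply(1:8, function(k)
  simulate_chain(initial_string_set(k), n_generations = 10,
                 seed = 100 + k, chain_id = paste0("chain", k)))
run_report(chains)
#> <chain_report: 8 chain(s), generations 1..10>
#> Across-chain means (first and last generation):
#>       measure generation    mean    sem n_chains
#>    acs_global          1  0.0851 0.0017        8
#>    acs_global         10  0.3662 0.0183        8
#>  global_error          1  0.1664 0.0265        8
#>  global_error         10  0.0071 0.0027        8
#>   mean_length          1  4.0667 0.0642        8
#>   mean_length         10  4.0500 0.1200        8
#>     n_correct          1  9.2500 0.7962        8
#>     n_correct         10 14.5000 0.1890        8
#> Tests:
#>       measure         comparison       t df        p       method
#>  global_error generation 1 vs 10  -6.133  7 4.75e-04     paired_t
#>  global_error              trend -11.083  7 1.08e-05 chain_slopes
#>     n_correct generation 1 vs 10   6.788  7 2.56e-04     paired_t
#>     n_correct              trend  12.529  7 4.76e-06 chain_slopes
#>   mean_length generation 1 vs 10  -0.224  7 8.29e-01     paired_t
#>   mean_length              trend  -0.084  7 9.35e-01 chain_slopes
#>    acs_global generation 1 vs 10  15.664  7 1.05e-06     paired_t
#>    acs_global              trend  13.352  7 3.10e-06 chain_slopes
```

Reading the report: across generations, global error falls (0.166 → 0.007)
and chunk reuse rises (ACS 0.085 → 0.366) while mean string length stays
flat around 4 — structure, not shrinkage, is what makes the sets easier to
recall. The network view shows the same transition: at generation 0 the
shuffle null is *more* connected than the unstructured originals,

```r
shuffle_comparison(initial_string_set(1), n_shuffles = 100, seed = 7)
#> <shuffle_comparison: stringset, 100 shuffles>
#>   mean connectivity: original=0.1333 shuffled=0.2043
```

whereas evolved final-generation sets out-connect their shuffled baselines
(see `scaling_fit()` for the connectivity-by-length regression that
quantifies this).

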