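Package: seqchains
Title: Iterated-Learning Analysis of Sequence Memory Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the cultural evolution of sequence structure in
    iterated-learning (diffusion-chain) recall experiments. Provides constrained
    generation and validation of consonant string sets, Levenshtein-based
    learnability scoring against the closest training item, Associative Chunk
    Strength (ACS) from bigram/trigram fragment tables, bigram-sharing reuse
    networks with within-string shuffle null models and connectivity-by-length
    scaling regressions, comparison-sequence baselines (digit strings from
    frequencies, password digit runs, resampled digit windows), first-versus-last
    paired t-tests and cross-generation trend tests, and a chunk-based learner
    simulator that produces transmission chains with the statistical signatures
    the analyses are designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    sandwich,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
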