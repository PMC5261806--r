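test_that("learner_config validates its parameters", {
  cfg <- learner_config()
  expect_equal(cfg$n_blocks, 6L)
  expect_equal(cfg$reuse_bias, 1.5)
  expect_equal(cfg$verbatim_gain, c(-1, 2))
  expect_equal(cfg$symbol_noise, 0.05)
  expect_error(learner_config(reuse_bias = -1), "reuse_bias")
  expect_error(learner_config(symbol_noise = 1.2), "probability")
  expect_error(learner_config(n_blocks = 0), "positive integer")
})

test_that("simulated chains keep the transmission contract", {
  ch <- simulate_chain(initial_string_set(1), n_generations = 5, seed = 17,
                       chain_id = "sim1")
  expect_s3_class(ch, "chain")
  expect_equal(n_generations(ch), 5L)
  for (g in 0:5) {
    s <- generation(ch, g)
    expect_length(s, 15L)
    expect_false(anyDuplicated(as.character(s)) > 0)
    expect_true(all(unlist(s$items) %in% s$alphabet))
  }
  ch2 <- simulate_chain(initial_string_set(1), n_generations = 5, seed = 17)
  expect_identical(lapply(ch$generations, as.character),
                   lapply(ch2$generations, as.character))
  dup <- string_set(c("AAA", "AAA", "BBB"), kind = "experiment")
  expect_error(simulate_chain(dup, n_generations = 1), "unique")
})

test_that("full initial-set validation can be demanded for the seed set", {
  ok <- generate_initial_set(c("B", "C", "D", "F", "G", "H"), seed = 3)
  ch <- simulate_chain(ok, n_generations = 1, seed = 1, validate = "full")
  expect_equal(n_generations(ch), 1L)
  # a structurally legal but constraint-violating seed is rejected under "full"
  loose <- string_set(c(sprintf("AB%s", LETTERS[1:5]),
                        sprintf("ABC%s", LETTERS[1:5]),
                        sprintf("ABCD%s", LETTERS[1:5])), kind = "experiment")
  expect_error(simulate_chain(loose, n_generations = 1, validate = "full"),
               "fails full")
})

test_that("end-to-end: a simulated chain yields finite statistics in every module", {
  ch <- simulate_chain(initial_string_set(2), n_generations = 6, seed = 23)
  m <- chain_metrics(ch)
  expect_equal(nrow(m), 6L)
  expect_true(all(is.finite(m$global_error)))
  expect_true(all(is.finite(m$acs_global)))
  expect_true(all(m$global_error >= 0 & m$global_error <= 1))
  expect_true(all(m$n_correct >= 0 & m$n_correct <= 15))
  cmp <- shuffle_comparison(generation(ch, 6), n_shuffles = 20, seed = 1)
  fit <- scaling_fit(cmp$records)
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_s3_class(trend_test(data.frame(chain = rep(1:2, each = 6),
                                        generation = rep(1:6, 2),
                                        value = c(m$acs_global,
                                                  m$acs_global + rnorm(6, 0, .01)))),
                  "trend_result")
})

test_that("pos grammar configs validate transition matrices", {
  expect_error(pos_grammar_config(transition = matrix(1, 2, 2)), "15 x 15")
  bad <- matrix(1 / 15, 15, 15)
  bad[1, 1] <- bad[1, 1] + 1e-6
  expect_error(pos_grammar_config(transition = bad), "sum to 1")
  cfg <- pos_grammar_config(n = 50)
  expect_equal(rowSums(cfg$transition), setNames(rep(1, 15), cfg$tags))
})

test_that("synthetic pos corpora have the configured lengths and tag alphabet", {
  corp <- generate_pos_corpus(pos_grammar_config(n = 80), seed = 12)
  expect_length(corp, 80L)
  expect_true(all(item_lengths(corp) %in% 3:6))
  expect_true(all(unlist(corp$items) %in% corp$alphabet))
  corp2 <- generate_pos_corpus(pos_grammar_config(n = 80), seed = 12)
  expect_identical(as.character(corp), as.character(corp2))
})

test_that("a degenerate transition matrix yields fully repetitive strings", {
  k <- 15
  tm <- matrix(0, k, k)
  tm[, 1] <- 1
  cfg <- pos_grammar_config(transition = tm, n = 30)
  corp <- generate_pos_corpus(cfg, seed = 4)
  expect_true(all(vapply(corp$items, function(x) all(x == x[1]), logical(1))))
  # permutation-invariant strings: original and shuffled networks coincide
  sh <- shuffle_within_strings(corp, seed = 5)
  expect_equal(edge_key(build_reuse_network(sh)),
               edge_key(build_reuse_network(corp)))
})

test_that("structured transitions produce more original than shuffled connectivity", {
  diffs <- vapply(1:20, function(s) {
    tm <- random_transition_matrix(15, concentration = 0.08, seed = 100 + s)
    corp <- generate_pos_corpus(pos_grammar_config(transition = tm, n = 120),
                                seed = 200 + s)
    cmp <- shuffle_comparison(corp, n_shuffles = 5, seed = 300 + s)
    cmp$mean_connectivity[["original"]] - cmp$mean_connectivity[["shuffled"]]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("random digit streams are deterministic and uniform", {
  st <- random_digit_stream(20000, seed = 7)
  expect_length(st, 20000L)
  expect_identical(random_digit_stream(50, seed = 1)$symbols,
                   random_digit_stream(50, seed = 1)$symbols)
  p <- stats::chisq.test(table(st$symbols))$p.value
  expect_gt(p, 0.001)
})
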