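test_that("string_set construction, coercion and basic accessors work", {
  s <- string_set(c("cmc", "SFL"), kind = "experiment")
  expect_s3_class(s, "string_set")
  expect_equal(as.character(s), c("CMC", "SFL"))
  expect_equal(s$alphabet, c("C", "F", "L", "M", "S"))
  expect_equal(item_lengths(s), c(3L, 3L))

  tok <- string_set(list(c("noun", "verb"), c("verb", "noun", "noun")))
  expect_equal(as.character(tok), c("noun verb", "verb noun noun"))
  expect_equal(length(tok), 2L)

  expect_error(string_set(list(character(0))), "at least one symbol")
  expect_error(string_set("ABC", alphabet = c("A", "B")), "outside the declared alphabet")
  expect_error(string_set("AB", alphabet = c("A", "A", "B")), "distinct")
})

test_that("the published initial sets parse to 15 unique strings of the 5/5/5 length design", {
  sets <- initial_string_sets()
  expect_length(sets, 8L)
  for (s in sets) {
    rep <- validate_initial_set(s)
    expect_equal(rep$n_items, 15L)
    expect_true(rep$checks[["items_unique"]])
    expect_true(rep$checks[["length_histogram"]])
    expect_true(rep$checks[["alphabet_size"]])
    expect_true(rep$checks[["total_symbols"]])
    expect_true(rep$checks[["max_bigram"]])
    expect_true(rep$checks[["max_trigram"]])
  }
  # chain 1 letter counts are exactly uniform
  expect_true(all(validate_initial_set(sets$chain1)$symbol_counts == 10))
  expect_setequal(names(validate_initial_set(sets$chain1)$symbol_counts),
                  c("C", "M", "S", "F", "L", "P"))
})

test_that("published sets with uneven printed letter counts are flagged on uniformity only", {
  # chains 3 and 6 as published have one letter at 9 and one at 11 occurrences
  for (k in c(3L, 6L)) {
    rep <- validate_initial_set(initial_string_set(k))
    expect_false(rep$checks[["symbol_uniformity"]])
    expect_true(all(rep$checks[setdiff(names(rep$checks), "symbol_uniformity")]))
    expect_equal(sort(as.integer(rep$symbol_counts)), c(9L, 10L, 10L, 10L, 10L, 11L))
  }
})

test_that("validation counts violations and rejects malformed input", {
  s <- initial_string_set(1)
  expect_error(validate_initial_set(s[0]), "empty")
  # dropping a string breaks the item count
  rep <- validate_initial_set(s[-1])
  expect_false(rep$passes)
  expect_equal(rep$n_items, 14L)
  # a bigram occurring 4 times across strings breaks the cap
  bad <- string_set(c("ABA", "ABB", "BAB", "AAB", "BBA",
                      "ABBA", "BABA", "AABB", "BBAA", "BAAB",
                      "AABBA", "BBAAB", "ABABA", "BABAB", "AAABB"),
                    kind = "experiment")
  rep_bad <- validate_initial_set(bad)
  expect_false(rep_bad$passes)
  expect_gt(rep_bad$max_bigram_repetition, 3L)
})

test_that("generate_initial_set yields valid, seed-deterministic, diverse sets", {
  alpha <- c("B", "C", "D", "F", "G", "H")
  expect_error(generate_initial_set(alpha[1:5]), "6 distinct symbols")
  keys <- character(0)
  for (seed in 1:100) {
    s <- generate_initial_set(alpha, seed = seed)
    expect_true(validate_initial_set(s)$passes)
    keys <- c(keys, paste(sort(as.character(s)), collapse = "|"))
  }
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(as.character(generate_initial_set(alpha, seed = 7)),
                   as.character(generate_initial_set(alpha, seed = 7)))
})

test_that("remap_symbols is a structure-preserving bijection with error checks", {
  s <- initial_string_set(1)
  ident <- setNames(s$alphabet, s$alphabet)
  expect_equal(as.character(remap_symbols(s, ident)), as.character(s))

  swap <- setNames(s$alphabet, s$alphabet)
  swap[c("C", "M")] <- c("M", "C")
  r <- remap_symbols(s, swap)
  expect_true(validate_initial_set(r)$passes)
  expect_equal(item_lengths(r), item_lengths(s))
  # remapped probe scores identically in remapped space
  tab_s <- fragment_table(s, mode = "raw_count")
  tab_r <- fragment_table(r, mode = "raw_count")
  expect_equal(acs_item("CMC", tab_s), acs_item("MCM", tab_r))

  expect_error(remap_symbols(s, setNames(rep("X", 6), s$alphabet)), "not injective")
  expect_error(remap_symbols(s, c(C = "K")), "does not cover")
})

test_that("filter_by_length selects exactly the in-range items in order", {
  s <- string_set(c("AB", "ABC", "ABCDEF", "ABCDEFG"))
  expect_equal(as.character(filter_by_length(s, 3, 6)), c("ABC", "ABCDEF"))
  expect_equal(as.character(filter_by_length(s, 1, Inf)), as.character(s))
  expect_length(filter_by_length(s, 10, 20), 0L)
  expect_error(filter_by_length(s, 5, 3), "must not exceed")
  # the published chain 2 set has exactly these five length-5 strings
  f <- filter_by_length(initial_string_set(2), 5, 5)
  expect_setequal(as.character(f), c("BZTSV", "VBGSZ", "GVVZG", "SSGBB", "ZGZVZ"))
})
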