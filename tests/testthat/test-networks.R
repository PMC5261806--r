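test_that("shares_bigram implements bigram-set intersection", {
  expect_true(shares_bigram("215686", "83915"))
  expect_false(shares_bigram("1492", "123456"))
  for (s in c("AB", "QZM", "215686")) expect_true(shares_bigram(s, s))
  expect_false(shares_bigram("A", "AB"))
})

test_that("reuse networks connect strings sharing at least one bigram", {
  expect_equal(igraph::ecount(build_reuse_network(c("ABC", "ABD"))), 1L)
  expect_equal(igraph::ecount(build_reuse_network(c("AB", "CD", "EF"))), 0L)
  g3 <- build_reuse_network(c("ABC", "BCA", "CAB"))
  expect_equal(igraph::ecount(g3), 3L)
  # duplicates collapse to unique string types; length-1 strings are isolated
  g <- build_reuse_network(c("ABC", "ABC", "A"))
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::degree(g, "A"), c(A = 0))
  expect_equal(igraph::vertex_attr(g, "length"), c(3L, 1L))
  expect_identical(igraph::graph_attr(g, "provenance"), "original")
})

test_that("connectivity records are degree over (n - 1)", {
  full <- connectivity_records(build_reuse_network(c("ABC", "ABD", "ABE", "ABF")))
  expect_true(all(full$proportion_connected == 1))
  star <- connectivity_records(build_reuse_network(c("ABCDE", "AAB", "BCC", "DDE")))
  expect_equal(star$proportion_connected[star$string == "ABCDE"], 1)
  expect_equal(star$proportion_connected[star$string != "ABCDE"], rep(1 / 3, 3))
  iso <- connectivity_records(build_reuse_network(c("AB", "CD", "EF")))
  expect_true(all(iso$proportion_connected == 0))
  expect_error(connectivity_records(build_reuse_network("ABC")), "fewer than 2")
})

test_that("within-string shuffling conserves lengths and per-string multisets", {
  s <- initial_string_set(7)
  sh <- shuffle_within_strings(s, seed = 5)
  expect_equal(item_lengths(sh), item_lengths(s))
  for (i in seq_along(s$items)) {
    expect_equal(sort(sh$items[[i]]), sort(s$items[[i]]))
  }
  expect_equal(as.character(shuffle_within_strings(s, seed = 9)),
               as.character(shuffle_within_strings(s, seed = 9)))
  expect_equal(as.character(shuffle_within_strings(string_set("AAA"), seed = 1)),
               "AAA")
})

test_that("scaling_fit recovers constructed condition and interaction effects", {
  lens <- rep(3:6, each = 10)
  mk <- function(slope, cond) {
    data.frame(string = paste0(cond, seq_along(lens)), length = lens,
               proportion_connected = slope * lens, condition = cond,
               source = "constructed", replicate = NA_integer_)
  }
  # identical generating process in both conditions: no condition effect
  # (noise-free input triggers lm's perfect-fit warning)
  null_fit <- suppressWarnings(
    scaling_fit(rbind(mk(0.1, "original"), mk(0.1, "shuffled"))))
  expect_equal(null_fit$coefficients["condition", "estimate"], 0, tolerance = 1e-10)
  expect_equal(null_fit$coefficients["length_x_condition", "estimate"], 0,
               tolerance = 1e-10)
  # doubled slope in the original condition: interaction is exactly the difference
  eff_fit <- suppressWarnings(
    scaling_fit(rbind(mk(0.10, "original"), mk(0.05, "shuffled"))))
  expect_equal(eff_fit$coefficients["length_x_condition", "estimate"], 0.05,
               tolerance = 1e-10)
  expect_equal(eff_fit$coefficients["length", "estimate"], 0.05, tolerance = 1e-10)
  # degenerate designs are named
  one_len <- rbind(mk(0.1, "original"), mk(0.1, "shuffled"))
  one_len$length <- 4
  expect_error(scaling_fit(one_len), "length term collapsed")
  expect_error(scaling_fit(mk(0.1, "original")), "condition term collapsed")
  # cluster-robust errors are available and keep the estimates
  # noise-free input triggers lm's perfect-fit warning inside the sandwich call
  cl <- suppressWarnings(
    scaling_fit(rbind(mk(0.10, "original"), mk(0.05, "shuffled")), cluster = TRUE))
  expect_equal(cl$coefficients$estimate, eff_fit$coefficients$estimate)
})

test_that("network topology is invariant under bijective remapping", {
  s <- initial_string_set(8)
  net <- build_reuse_network(s)
  mapping <- setNames(c("B", "C", "D", "F", "G", "H"), s$alphabet)
  net_r <- build_reuse_network(remap_symbols(s, mapping))
  rename <- function(x) {
    vapply(strsplit(x, ""), function(sym) paste(mapping[sym], collapse = ""),
           character(1))
  }
  expect_equal(edge_key(net_r), edge_key(net, rename))
  expect_equal(sort(igraph::degree(net_r)), sort(igraph::degree(net)),
               ignore_attr = TRUE)
})

test_that("shuffle_comparison pools replicate-tagged records for the regression", {
  cmp <- shuffle_comparison(initial_string_set(1), n_shuffles = 10, seed = 2)
  expect_equal(sum(cmp$records$condition == "original"), 15L)
  expect_equal(sum(cmp$records$condition == "shuffled"), 150L)
  expect_equal(sort(unique(cmp$records$replicate)), 1:10)
  fit <- scaling_fit(cmp$records)
  expect_s3_class(fit, "scaling_fit")
  expect_equal(fit$n, 165L)
})

test_that("similarity layout returns coordinates for every node and inverse-distance weights", {
  s <- string_set(c("ABC", "ABD", "XYZ", "XYW"))
  lay <- similarity_layout(s, seed = 3)
  expect_equal(nrow(lay$coords), 4L)
  expect_true(all(is.finite(lay$coords$x)))
  expect_equal(lay$edges$weight,
               1 / (1 + mapply(edit_distance, lay$edges$from, lay$edges$to)),
               ignore_attr = TRUE)
  # the ABC-ABD pair is at edit distance 1, hence weight 1/2
  ab <- lay$edges[lay$edges$from %in% c("ABC", "ABD") &
                    lay$edges$to %in% c("ABC", "ABD"), ]
  expect_equal(ab$weight, 0.5)
  # an edgeless set still gets one coordinate per node
  lay0 <- similarity_layout(c("AB", "CD", "EF"), seed = 1)
  expect_equal(nrow(lay0$coords), 3L)
  expect_equal(nrow(lay0$edges), 0L)
})

test_that("mean connectivity does not decrease with expected string length", {
  set.seed(14)
  alpha <- LETTERS[1:6]
  mean_conn <- function(len) {
    vals <- replicate(30, {
      items <- replicate(15, paste(sample(alpha, len, replace = TRUE), collapse = ""))
      mean(connectivity_records(build_reuse_network(unique(items)))$proportion_connected)
    })
    mean(vals)
  }
  expect_gt(mean_conn(5), mean_conn(3))
})
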