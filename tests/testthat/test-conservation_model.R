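test_that("random conservation is the product of species frequencies", {
  expect_equal(round(random_position_conservation(0.597, 0.570), 4), 0.3403)
  expect_equal(random_position_conservation(1, 1), 1)
  expect_equal(random_position_conservation(0.5, 0), 0)
  expect_error(random_position_conservation(1.2, 0.5), "0, 1")
})

test_that("actual conservation counts couples carrying the base in both", {
  pairs <- pairs_from_seqs(
    c(intron_seq("GTAAGT"), intron_seq("GTAAGT")),
    c(intron_seq("GTAAGT"), intron_seq("GTGAGT"))
  )
  hx <- extract_hexes(pairs)
  expect_equal(actual_position_conservation(hx, "five_prime", 3, "A"), 0.5)
  expect_equal(actual_position_conservation(hx, "five_prime", 4, "A"), 1)
  expect_error(actual_position_conservation(hx, "five_prime", 1, "G"),
               "not variable")
  # partition identity: sum over bases = fraction identical at the position
  sim <- generate_pairs(generator_config(n_pairs = 150, seed = 5,
                                         intron_length_range = c(20, 40)))
  shx <- extract_hexes(sim$pairs)
  prof <- identity_profile(sim$pairs, "five_prime", window = 6)
  for (p in 3:6) {
    by_base <- vapply(c("A", "C", "G", "T"), function(b) {
      actual_position_conservation(shx, "five_prime", p, b)
    }, numeric(1))
    expect_equal(sum(by_base), prof$identity[p])
  }
})

test_that("motif patterns validate their shape and infer their end", {
  expect_equal(motif_pattern("GTGAGx")$end, "five_prime")
  expect_equal(motif_pattern("TTxxAG")$end, "three_prime")
  expect_error(motif_pattern("GTxxxx"), "at least one variable")
  expect_error(motif_pattern("xxxxxx"), "invariant")
  expect_error(motif_pattern("GTACAG"), "bifunctional")
  expect_equal(motif_pattern("GTACAG", "five_prime")$fixed_variable, 3:6)
  expect_error(motif_pattern("ATGAGx"), "invariant")
  expect_error(motif_pattern("GTGAG"), "6-character")
  expect_error(motif_pattern("GTGAGZ"), "A, C, G, T or x")
})

test_that("motif random probability multiplies fixed-position conservation", {
  ref5 <- reference_conservation("five_prime")
  ref3 <- reference_conservation("three_prime")
  expect_equal(motif_random_probability("GTAAGT", ref5),
               0.5093 * 0.7778 * 0.8241 * 0.4537)
  expect_equal(motif_random_probability("GTAAGx", ref5),
               0.5093 * 0.7778 * 0.8241)
  expect_equal(motif_random_probability("TTxxAG", ref3), 0.4259 * 0.4861)
  expect_error(motif_random_probability("TTxxAG", ref5), "three_prime")
})

test_that("motif actual frequency matches hand counts and the regex oracle", {
  pairs <- pairs_from_seqs(
    c(intron_seq("GTGAGT"), intron_seq("GTGAGT")),
    c(intron_seq("GTGAGT"), intron_seq("GTAAGT"))
  )
  hx <- extract_hexes(pairs)
  expect_equal(motif_actual_frequency(hx, "GTGAGx"), 0.5)
  expect_equal(motif_actual_frequency(hx, "GTGAGT"), 0.5)

  # fully-fixed pattern equals the conserved-hexanucleotide frequency
  sim <- generate_pairs(generator_config(n_pairs = 20, seed = 13,
                                         intron_length_range = c(20, 30)))
  shx <- extract_hexes(sim$pairs)
  h5 <- shx[shx$end == "five_prime", ]
  top <- names(sort(table(h5$hex_a), decreasing = TRUE))[1]
  expect_equal(motif_actual_frequency(shx, top, end = "five_prime"),
               mean(h5$hex_a == top & h5$hex_b == top))

  # equivalence with an independent regex-counting oracle, all 624 patterns
  for (end in c("five_prime", "three_prime")) {
    he <- shx[shx$end == end, ]
    pats <- enumerate_motif_patterns(end)
    mine <- vapply(pats, function(p) motif_actual_frequency(shx, p, end),
                   numeric(1))
    oracle <- vapply(pats, function(p) {
      brute_motif_frequency(he$hex_a, he$hex_b, p)
    }, numeric(1))
    expect_equal(unname(mine), unname(oracle))
  }
})

test_that("binomial SD uses the count scale", {
  expect_equal(round(binomial_sd(216, 0.2070), 2), 5.95)
  expect_equal(round(binomial_sd(216, 0.0345), 2), 2.68)
  expect_equal(binomial_sd(100, 0), 0)
  expect_error(binomial_sd(0, 0.5), "n")
})

test_that("binomial tails match the brute-force summation oracle", {
  expect_equal(binomial_tail_test(7, 7, 0.3, "lower"), 1)
  expect_equal(binomial_tail_test(0, 216, 0.1929, "lower"),
               (1 - 0.1929)^216)
  for (n in c(1, 7, 23, 50)) {
    for (p0 in c(0.0345, 0.1929, 0.5)) {
      for (k in 0:n) {
        expect_equal(binomial_tail_test(k, n, p0, "upper"),
                     brute_binomial_tail(k, n, p0, "upper"),
                     tolerance = 1e-12)
        expect_equal(binomial_tail_test(k, n, p0, "lower"),
                     brute_binomial_tail(k, n, p0, "lower"),
                     tolerance = 1e-12)
      }
    }
  }
  # degenerate nulls
  expect_equal(binomial_tail_test(0, 10, 0, "upper"), 1)
  expect_equal(binomial_tail_test(3, 10, 0, "upper"), 0)
  expect_equal(binomial_tail_test(3, 10, 0, "lower"), 1)
  expect_equal(binomial_tail_test(10, 10, 1, "lower"), 1)
  expect_equal(binomial_tail_test(9, 10, 1, "lower"), 0)
  expect_error(binomial_tail_test(11, 10, 0.5), "k must")
})

test_that("conservation_table is internally consistent", {
  sim <- generate_pairs(generator_config(n_pairs = 200, seed = 17,
                                         intron_length_range = c(20, 40)))
  hx <- extract_hexes(sim$pairs)
  for (end in c("five_prime", "three_prime")) {
    ct <- conservation_table(hx, end)
    expect_equal(nrow(ct), 16L)
    expect_true(all(ct$random_cons <= pmin(ct$freq_a, ct$freq_b) + 1e-12))
    expect_equal(ct$random_cons, ct$freq_a * ct$freq_b)
    expect_true(all(ct$p_value > 0 & ct$p_value <= 1))
    tot <- attr(ct, "totals")
    expect_true(all(tot$random_total <= 1 & tot$actual_total <= 1))
  }
})

test_that("motif_scan enumerates 624 patterns with refinement monotonicity", {
  sim <- generate_pairs(generator_config(n_pairs = 100, seed = 23,
                                         intron_length_range = c(20, 30)))
  hx <- extract_hexes(sim$pairs)
  scan <- motif_scan(hx, "five_prime")
  expect_equal(nrow(scan), 624L)
  expect_equal(sum(choose(4, 1:4) * 4^(1:4)), 624)
  expect_true(!is.unsorted(scan$p_value))
  expect_equal(scan$direction == "over", scan$excess > 0)
  # refining a pattern (fixing one more position) never increases either
  # the random probability or the actual frequency
  lut_rand <- setNames(scan$random_prob, scan$pattern)
  lut_act <- setNames(scan$actual_freq, scan$pattern)
  set.seed(1)
  coarse <- sample(scan$pattern[scan$n_fixed < 4], 40)
  for (pat in coarse) {
    wild <- which(strsplit(pat, "")[[1]] == "x" & seq_len(6) %in% 3:6)
    p <- wild[1]
    for (b in c("A", "C", "G", "T")) {
      fine <- pat
      substr(fine, p, p) <- b
      expect_lte(lut_rand[[fine]], lut_rand[[pat]] + 1e-12)
      expect_lte(lut_act[[fine]], lut_act[[pat]] + 1e-12)
    }
  }
})

test_that("motif_scan on a single couple gives frequency 1 for its pattern", {
  hx <- extract_hexes(pairs_from_seqs(intron_seq("GTGAGT"),
                                      intron_seq("GTGAGT")))
  scan <- motif_scan(hx, "five_prime")
  expect_equal(scan$actual_freq[scan$pattern == "GTGAGT"], 1)
})

test_that("species composition test follows the count excess", {
  oracle <- brute_binomial_tail(25, 216, 16 / 216, "upper")
  expect_equal(species_composition_test(25, 16, 216), oracle)
  expect_gte(species_composition_test(20, 20, 216), 0.5)
  # symmetric contract: direction follows the sign of the difference
  expect_equal(species_composition_test(25, 16, 216),
               species_composition_test(16, 25, 216))
  expect_error(species_composition_test(300, 10, 216), "counts")
})
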