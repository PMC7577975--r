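test_that("pair classification covers the class taxonomy", {
  wc <- classify_pair("G", "C", TRUE)
  expect_equal(wc$kind, "WC")
  expect_equal(wc$identity_symmetric, "G-C")
  wob <- classify_pair("U", "G", TRUE)
  expect_equal(wob$kind, "WOBBLE")
  expect_equal(wob$identity_symmetric, "G-U")
  mm <- classify_pair("C", "C", FALSE)
  expect_equal(mm$kind, "MISMATCH")
  expect_equal(mm$identity_symmetric, "C-C")
  # orientation preserved in ordered, collapsed in symmetric
  ua <- classify_pair("U", "A", TRUE)
  expect_equal(ua$identity_ordered, "U-A")
  expect_equal(ua$identity_symmetric, "A-U")
  bg <- classify_pair("A", NA, FALSE)
  expect_equal(bg$kind, "BULGE")
  expect_equal(bg$identity_ordered, "bulge5")
  # a paired non-canonical combination is an engine inconsistency
  expect_error(classify_pair("A", "A", TRUE, "recX"), "recX")
})

test_that("single-alignment compositions are degenerate columns of 100", {
  hp <- planned_hairpin(c("P", "P", "P", "P"))
  aln <- register_arms(hp$dotbracket, hp$sequence, c(1, 4), c(9, 12))
  ov <- overall_composition(list(aln), mode = "kind")
  expect_equal(ov$values["WC", "overall"], 100)
  expect_equal(sum(ov$values[, 1]), 100)
  sc <- site_composition(list(aln), coords = 1:3)
  expect_true(all(colSums(sc$values) == 100))
  expect_true(all(apply(sc$values, 2, function(x) sum(x > 0)) == 1))
})

test_that("frequency columns always sum to 100 within tolerance", {
  alns <- lapply(1:15, function(s)
    register_generated(generate_precursor(syn_quick(seed = s), seed = s)))
  for (mode in c("kind", "symmetric", "ordered")) {
    ov <- overall_composition(alns, mode = mode)
    expect_lt(abs(sum(ov$values[, 1]) - 100), 0.01)
  }
  sc <- site_composition(alns, coords = c(-5L, -1L, 1L, 2L, 3L, 21L, 24L),
                         mode = "symmetric")
  expect_true(all(abs(colSums(sc$values) - 100) < 0.01))
  expect_true(all(sc$n_per_position <= length(alns)))
})

test_that("symmetric-mode matrices are invariant under arm swap", {
  alns <- lapply(1:10, function(s)
    register_generated(generate_precursor(syn_quick(seed = 100 + s),
                                          seed = 100 + s)))
  swap <- lapply(alns, function(a) {
    b <- a
    nt5 <- b$nt5; b$nt5 <- b$nt3; b$nt3 <- nt5
    s5 <- b$src5; b$src5 <- b$src3; b$src3 <- s5
    b
  })
  m1 <- site_composition(alns, coords = c(-1L, 1L, 2L, 3L), mode = "symmetric")
  m2 <- site_composition(swap, coords = c(-1L, 1L, 2L, 3L), mode = "symmetric")
  # bulge sidedness aside, symmetric identities are orientation-free
  expect_equal(m1$values, m2$values)
})

test_that("mismatch-position counting pools across precursors", {
  # five planted mismatches per precursor, twenty precursors
  planted <- setNames(lapply(1:5, function(i) c("U-U" = 1)),
                      as.character(c(2, 5, 9, 13, 17)))
  sp <- synthetic_spec(n_records = 20, seed = 3, planted = planted,
                       stem_identity = c("G-C" = 0.6, "A-U" = 0.4),
                       duplex_identity = c("G-C" = 0.6, "A-U" = 0.4))
  gens <- lapply(1:20, function(i) generate_precursor(sp, seed = 3 + i))
  alns <- lapply(gens, register_generated)
  cnt <- count_mismatch_positions(alns)
  expect_equal(cnt$n_positions, 100)
  expect_equal(cnt$n_precursors, 20)
  # perfectly paired set has none
  sp2 <- synthetic_spec(n_records = 3, seed = 9,
                        stem_identity = c("G-C" = 0.6, "A-U" = 0.4),
                        duplex_identity = c("G-C" = 0.6, "A-U" = 0.4))
  alns2 <- lapply(1:3, function(i)
    register_generated(generate_precursor(sp2, seed = 9 + i)))
  cnt2 <- count_mismatch_positions(alns2)
  expect_equal(cnt2$n_positions, 0)
  expect_equal(cnt2$n_precursors, 0)
})

test_that("independence null reduces to p(x)p(y) with zero enrichment at equality", {
  unif <- setNames(rep(0.25, 4), c("A", "C", "G", "U"))
  null <- expected_pair_frequencies(unif)
  expect_equal(unname(null$expected_ordered),
               rep(6.25, 16))
  comp <- c(A = 0.2, C = 0.3, G = 0.25, U = 0.25)
  null2 <- expected_pair_frequencies(comp)
  expect_equal(unname(null2$expected_ordered["C-C"]), 9)
  expect_equal(sum(null2$expected_ordered), 100)
  expect_equal(sum(null2$expected_symmetric), 100)

  # observed == expected -> all enrichments zero, chi-square zero
  counts <- matrix(round(null$expected_ordered / 100 * 1600), ncol = 1,
                   dimnames = list(names(null$expected_ordered), "overall"))
  obs <- mirduplex:::new_pair_freq_matrix(
    values = counts / sum(counts) * 100, counts = counts,
    n_per_position = c(overall = sum(counts)), mode = "ordered",
    n_precursors = 10L)
  res <- expected_pair_frequencies(unif, observed = obs)
  expect_equal(unname(res$enrichment_log2[, 1]), rep(0, 16), tolerance = 1e-12)
  expect_equal(unname(res$chisq), 0, tolerance = 1e-12)

  expect_error(expected_pair_frequencies(c(A = 0.5, C = 0.5, G = 0.2,
                                           U = 0.2)), "sum to 1")
})

test_that("group comparison flags planted differences and is null on self", {
  alns <- lapply(1:12, function(s)
    register_generated(generate_precursor(syn_quick(seed = 200 + s),
                                          seed = 200 + s)))
  m <- site_composition(alns, coords = c(1L, 2L))
  self <- compare_groups(m, m)
  expect_true(all(self$diff == 0))
  expect_true(all(self$p_adj >= 0.99))

  # plant a 100 vs 0 G-C difference at coordinate 1 in two cohorts
  spA <- synthetic_spec(n_records = 40, seed = 1,
                        planted = list(`1` = c("G-C" = 1)))
  spB <- synthetic_spec(n_records = 40, seed = 1,
                        planted = list(`1` = c("U-U" = 1)))
  alnA <- lapply(1:40, function(i)
    register_generated(generate_precursor(spA, seed = 1000 + i)))
  alnB <- lapply(1:40, function(i)
    register_generated(generate_precursor(spB, seed = 2000 + i)))
  mA <- site_composition(alnA, coords = c(-1L, 1L, 2L))
  mB <- site_composition(alnB, coords = c(-1L, 1L, 2L))
  d <- compare_groups(mA, mB)
  top <- d[which.max(abs(d$diff)), ]
  expect_equal(top$position, "1")
  expect_true(top$class %in% c("G-C", "U-U"))
  expect_lt(d$p_adj[d$class == "G-C" & d$position == "1"], 0.001)
})

test_that("conservation counting matches planted identities", {
  sp <- synthetic_spec(n_records = 15, seed = 77,
                       planted = list(`6` = c("C-C" = 1)))
  alns <- lapply(1:15, function(i)
    register_generated(generate_precursor(sp, seed = 500 + i)))
  cc <- conservation_count(alns, 6L, "C-C")
  expect_equal(cc$n_with, 15)
  expect_equal(cc$n_total, 15)
  none <- conservation_count(list(), 6L, "C-C")
  expect_equal(none$n_with, 0)
  expect_equal(none$n_total, 0)
})

test_that("planted per-position frequencies are recovered within binomial error", {
  n <- 150
  sp <- synthetic_spec(
    n_records = n, seed = 31,
    planted = list(`1` = c("G-C" = 0.6, "A-U" = 0.3, "U-U" = 0.1)))
  alns <- lapply(seq_len(n), function(i)
    register_generated(generate_precursor(sp, seed = 31 + i)))
  sc <- site_composition(alns, coords = 1L, mode = "symmetric")
  for (cl in c("G-C", "A-U", "U-U")) {
    p <- c("G-C" = 0.6, "A-U" = 0.3, "U-U" = 0.1)[[cl]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(sc$values[cl, "1"] / 100 - p), 3 * se + 1e-9)
  }
})
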