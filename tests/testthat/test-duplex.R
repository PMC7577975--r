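test_that("star inference obeys the 2-nt overhang law on a perfect hairpin", {
  db <- perfect_hairpin_db(23, 4)  # i pairs with 51-i for i <= 23
  star <- infer_star(db, c(3, 23))
  expect_equal(as.integer(star), c(30L, 50L))
  expect_false(attr(star, "clipped"))
  expect_false(attr(star, "interpolated"))
  # star length equals miRNA length
  expect_equal(diff(as.integer(star)), 23 - 3)
})

test_that("overhang law holds across stems, lengths and both arms", {
  for (stem in c(23, 30)) for (s in c(3, 4, 7)) {
    n <- 2 * stem + 4
    db <- perfect_hairpin_db(stem, 4)
    for (len in c(20, 21, 22)) {
      e <- s + len - 1
      if (e - 2 > stem) next  # keep the apical anchor on the 5' arm
      star <- infer_star(db, c(s, e))
      expect_equal(diff(as.integer(star)) + 1, len)
      # both duplex ends carry exactly 2-nt 3' overhangs:
      # star 5' end pairs with miRNA position e-2, star 3' end is 2 past
      # the partner of the miRNA 5' end
      pt <- parse_dotbracket(db)$pair_table
      expect_equal(star[1], pt[e - 2])
      expect_equal(star[2], pt[s] + 2)
      # symmetric roles: the miRNA inferred back from the star (on the 3'
      # arm) recovers the original interval
      back <- infer_star(db, as.integer(star))
      expect_equal(as.integer(back), c(s, e))
    }
  }
})

test_that("unpaired anchors are compensated from the nearest paired neighbor", {
  # perfect 23-bp stem with position 21 forced unpaired (and its partner 30)
  db_chars <- strsplit(perfect_hairpin_db(23, 4), "")[[1]]
  db_chars[c(21, 30)] <- "."
  db <- paste(db_chars, collapse = "")
  star <- infer_star(db, c(3, 23))
  # anchor miRNA_end - 2 = 21 is unpaired; nearest paired neighbor is 20
  # or 22 (both paired); compensation must land on the same registered
  # partner 30 as the exhaustive pairing table would give
  expect_equal(as.integer(star), c(30L, 50L))
  expect_true(attr(star, "interpolated"))
  expect_equal(diff(as.integer(star)), 20L)  # star length preserved

  # no paired anchor within 3 nt -> star_uninferrable
  db2 <- paste0(strrep("(", 10), strrep(".", 30), strrep(")", 10))
  expect_error(infer_star(db2, c(12, 32)), "no paired anchor")
})

test_that("registration emits paired, mismatch and bulge columns correctly", {
  hp <- planned_hairpin(c("P", "P", "M", "P", "B3", "P", "B5", "P", "P"))
  aln <- register_arms(hp$dotbracket, hp$sequence,
                       c(1, hp$n5), c(hp$n5 + 5, nchar(hp$sequence)))
  up <- aln[aln$coord >= 1, ]
  types <- ifelse(up$paired, "P",
                  ifelse(is.na(up$src3), "B5", ifelse(is.na(up$src5), "B3", "M")))
  expect_equal(types, hp$plan)
  # strand reconstruction: non-gap nt5 in order equals the 5' arm
  expect_equal(paste(up$nt5[!is.na(up$nt5)], collapse = ""),
               substr(hp$sequence, 1, hp$n5))
  # nt3 read in coord order is the reverse of the 3' arm subsequence
  arm3 <- substr(hp$sequence, nchar(hp$sequence) - hp$n3 + 1,
                 nchar(hp$sequence))
  expect_equal(paste(rev(up$nt3[!is.na(up$nt3)]), collapse = ""), arm3)
})

test_that("registration matches the exhaustive monotone-pairing oracle", {
  plans <- c(bulge_plans(5), bulge_plans(6))
  expect_gt(length(plans), 250)
  for (plan in plans) {
    hp <- planned_hairpin(plan)
    pt <- parse_dotbracket(hp$dotbracket)$pair_table
    aln <- register_arms(hp$dotbracket, hp$sequence,
                         c(1, hp$n5),
                         c(nchar(hp$sequence) - hp$n3 + 1, nchar(hp$sequence)))
    got <- alignment_to_cols(aln)
    want <- oracle_walk_up(pt, 1, nchar(hp$sequence))
    expect_equal(length(got), length(want),
                 info = paste(plan, collapse = ""))
    for (k in seq_along(want)) {
      expect_equal(got[[k]]$type, want[[k]]$type,
                   info = paste(paste(plan, collapse = ""), "col", k))
      expect_equal(as.integer(got[[k]]$i), want[[k]]$i,
                   info = paste(plan, collapse = ""))
      expect_equal(as.integer(got[[k]]$j), want[[k]]$j,
                   info = paste(plan, collapse = ""))
    }
  }
})

test_that("registration walks below the duplex into negative coordinates", {
  sp <- synthetic_spec(n_records = 1, seed = 5,
                       planted = list(`-3` = c("A-C" = 1),
                                      `-7` = c("bulge3" = 1)))
  g <- generate_precursor(sp, 5)
  aln <- register_generated(g)
  m3 <- aln[aln$coord == -3, ]
  expect_false(m3$paired)
  expect_setequal(c(m3$nt5, m3$nt3), c("A", "C"))
  m7 <- aln[aln$coord == -7, ]
  expect_true(is.na(m7$src5) && !is.na(m7$src3))
  expect_false(any(aln$coord == 0))
  expect_true(all(diff(aln$coord) %in% c(1L, 2L)))
})

test_that("role swap leaves the registered pairing set unchanged", {
  for (s in c(1, 9, 23)) {
    g <- generate_precursor(syn_quick(seed = s), seed = s)
    rec <- g$record
    struct <- parse_dotbracket(rec$structure)
    star <- infer_star(struct, rec$mirna_interval)
    a1 <- register_arms(struct, rec$sequence, rec$mirna_interval,
                        as.integer(star))
    a2 <- register_arms(struct, rec$sequence, as.integer(star),
                        rec$mirna_interval)
    expect_equal(as.data.frame(a1)[, c("src5", "src3", "paired")],
                 as.data.frame(a2)[, c("src5", "src3", "paired")])
  }
})

test_that("cleavage-site coordinates follow miRNA length and direction labels swap", {
  g <- generate_precursor(syn_quick(seed = 2), seed = 2)
  aln <- register_generated(g)
  s21 <- attr(assign_cleavage_coords(aln, "base_to_loop", 21L), "sites")
  expect_equal(s21$basal, c(-1L, 1L, 2L, 3L))
  expect_equal(s21$apical, 21:24)
  expect_equal(s21$first, s21$basal)
  s22 <- attr(assign_cleavage_coords(aln, "base_to_loop", 22L), "sites")
  expect_equal(s22$apical, 22:25)
  sl <- attr(assign_cleavage_coords(aln, "loop_to_base", 21L), "sites")
  expect_equal(sl$first, sl$apical)
  expect_equal(sl$second, sl$basal)
  expect_equal(sl$basal, s21$basal)  # coordinates do not move
  su <- attr(assign_cleavage_coords(aln, "unknown", 21L), "sites")
  expect_true(su$direction_assumed)
  expect_equal(su$first, su$basal)
})

test_that("alignment window is capped at 56 coordinates", {
  # an oversized hairpin: 80-bp perfect stem
  db <- perfect_hairpin_db(80, 4)
  sq <- perfect_hairpin_seq(80, 4)
  aln <- register_arms(db, sq, c(20, 40), c(127, 147))
  expect_lte(nrow(aln), 56)
  expect_equal(range(aln$coord), c(-15L, 41L))
  expect_true(attr(aln, "truncated"))
})
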