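test_that("generation is deterministic per (spec, seed)", {
  sp <- syn_quick(seed = 13)
  g1 <- generate_precursor(sp, 13)
  g2 <- generate_precursor(sp, 13)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$record$structure, g2$record$structure)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_precursor(sp, 14)
  expect_false(identical(g1$record$sequence, g3$record$sequence))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(generate_precursor(syn_quick(seed = 1), 1))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("an all-WC duplex yields a perfect stem and exact star recovery", {
  sp <- synthetic_spec(n_records = 1, seed = 4,
                       stem_identity = c("G-C" = 0.5, "A-U" = 0.5),
                       duplex_identity = c("G-C" = 0.5, "A-U" = 0.5))
  g <- generate_precursor(sp, 4)
  st <- parse_dotbracket(g$record$structure)
  # contiguous stem: every duplex position paired
  expect_true(all(st$pair_table[g$truth$mirna_interval[1]:
                                  g$truth$mirna_interval[2]] != 0))
  star <- infer_star(st, g$truth$mirna_interval)
  expect_equal(as.integer(star), as.integer(g$truth$star_interval))
  expect_equal(diff(as.integer(star)), diff(g$truth$mirna_interval))
})

test_that("planted classes are recovered exactly by the registration pipeline", {
  sp <- synthetic_spec(n_records = 1, seed = 21,
                       planted = list(`1` = c("C-C" = 1),
                                      `7` = c("G-U" = 1),
                                      `12` = c("bulge5" = 1)))
  for (s in c(21, 22, 23, 50)) {
    g <- generate_precursor(sp, s)
    aln <- register_generated(g)
    cls <- mirduplex:::classify_alignment(aln)
    tr <- g$truth$classes
    m <- merge(tr, cls, by = "coord")
    expect_equal(m$kind.y, m$kind.x)
    expect_equal(cls$symmetric[cls$coord == 1], "C-C")
    expect_equal(cls$symmetric[cls$coord == 7], "G-U")
    mism <- m$kind.x == "MISMATCH"
    expect_equal(m$symmetric[mism], m$identity[mism])
  }
})

test_that("surveys write valid files that reload into the same records", {
  dirn <- withr::local_tempdir()
  sp <- syn_quick(n = 6, seed = 8)
  out <- generate_survey(sp, dir = dirn)
  expect_true(all(file.exists(unlist(out$paths))))
  seqs <- read_fasta(out$paths$fasta)
  expect_length(seqs, 6)
  recs <- read_annotation_table(out$paths$annotation, out$paths$fasta,
                                structures = out$paths$dotbracket)
  expect_length(recs, 6)
  for (k in seq_along(recs)) {
    orig <- out$records[[k]]
    expect_equal(recs[[k]]$sequence, orig$sequence)
    expect_equal(recs[[k]]$structure, orig$structure)
    expect_equal(recs[[k]]$direction, orig$direction)
  }
  truth <- jsonlite::read_json(out$paths$truth, simplifyVector = TRUE)
  expect_length(truth, 6)

  # empty survey still writes valid files
  dir0 <- withr::local_tempdir()
  out0 <- generate_survey(synthetic_spec(n_records = 0), dir = dir0)
  expect_true(file.exists(out0$paths$annotation))
  expect_warning(expect_length(read_fasta(out0$paths$fasta), 0), "empty")
})

test_that("direction mix is reflected in the annotation", {
  sp <- synthetic_spec(n_records = 40, seed = 55,
                       direction_mix = c(base_to_loop = 0.5,
                                         loop_to_base = 0.5))
  gens <- lapply(1:40, function(i) generate_precursor(sp, seed = 55 + i))
  dirs <- vapply(gens, function(g) g$record$direction, character(1))
  truth_dirs <- vapply(gens, function(g) g$truth$direction, character(1))
  expect_identical(dirs, truth_dirs)
  expect_true(all(c("base_to_loop", "loop_to_base") %in% dirs))
})

test_that("MFE refolding reproduces the planted duplex pairing", {
  eng <- engine_config()
  skip_if_not(eng$available, "no folding engine on PATH")
  sp <- syn_quick(n = 10, seed = 123)
  agree <- vapply(1:10, function(i) {
    g <- generate_precursor(sp, seed = 123 + i)
    truth_pt <- parse_dotbracket(g$record$structure)$pair_table
    fold_pt <- fold_sequence(g$record$sequence, eng)$pair_table
    idx <- g$truth$mirna_interval[1]:g$truth$mirna_interval[2]
    mean(truth_pt[idx] == fold_pt[idx])
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("unsatisfiable identity specifications are rejected", {
  expect_error(synthetic_spec(planted = list(`1` = c("A-B" = 1))),
               "unknown identity")
  expect_error(synthetic_spec(planted = list(`1` = c("A-U" = 0.5))),
               "sum to 1")
  expect_error(synthetic_spec(loop_length = 2), "loop_length")
})
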