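SYN_IDENTITIES <- c("A-U", "G-C", "G-U", MISMATCH_SYM, "bulge5", "bulge3")

#' Specification for a synthetic precursor set
#'
#' Describes hairpins with a planted miRNA/miRNA* duplex: a basal
#' unstructured flank, a lower stem (the 15-17 bp dsRNA segment below
#' the duplex that guides base-to-loop processing; default 16 bp), the
#' duplex itself plus the region above it, a terminal loop, and the
#' mirror arm. Every registered coordinate carries a probability vector
#' over pair identities; defaults echo the class balance of natural
#' precursors (about 65% paired positions, G-U wobbles rarer than
#' Watson-Crick pairs, and among paired positions p(G-C) = 0.5,
#' p(A-U) = 0.4, p(G-U) = 0.1).
#'
#' @param n_records Number of precursors.
#' @param mirna_length miRNA length in nt (duplex coords 1..L).
#' @param lower_stem_length Paired coords below the duplex.
#' @param upper_ext Coords above the duplex (covers the apical cut;
#'   default 5).
#' @param loop_length Terminal loop length (>= 3).
#' @param flank_length Unstructured basal flank per side.
#' @param stem_identity Probability vector over identities for lower-stem
#'   coords (strongly paired by default so the planted fold dominates).
#' @param duplex_identity Probability vector over identities for duplex
#'   and upper coords.
#' @param planted Named list mapping coordinate (as character, e.g.
#'   `"1"`) to a probability vector over identities from
#'   `c("A-U","G-C","G-U","A-A","C-C","G-G","U-U","A-C","A-G","C-U",
#'   "bulge5","bulge3")`, overriding the defaults at that coordinate.
#' @param direction_mix Named probabilities over
#'   `c("base_to_loop", "loop_to_base")`.
#' @param seed Integer seed; generation is deterministic per
#'   (spec, seed).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records = 100L, mirna_length = 21L,
                           lower_stem_length = 16L, upper_ext = 5L,
                           loop_length = 8L, flank_length = 10L,
                           stem_identity = c("G-C" = 0.5, "A-U" = 0.4,
                                             "G-U" = 0.1),
                           duplex_identity = c(
                             c("G-C" = 0.40, "A-U" = 0.32, "G-U" = 0.08),
                             setNames(rep(0.2 / 7, 7), MISMATCH_SYM)),
                           planted = list(),
                           direction_mix = c(base_to_loop = 1,
                                             loop_to_base = 0),
                           seed = 1L) {
  check_identity_probs <- function(p, where) {
    if (is.null(names(p)) || any(!names(p) %in% SYN_IDENTITIES))
      stop("unknown identity in ", where, ": ",
           paste(setdiff(names(p), SYN_IDENTITIES), collapse = ", "))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("identity probabilities in ", where, " must be >= 0 and sum to 1")
  }
  check_identity_probs(stem_identity, "stem_identity")
  check_identity_probs(duplex_identity, "duplex_identity")
  for (nm in names(planted)) check_identity_probs(planted[[nm]],
                                                  paste0("planted[", nm, "]"))
  stopifnot(n_records >= 0, mirna_length >= 19, mirna_length <= 25,
            lower_stem_length >= 1, loop_length >= 3, flank_length >= 0,
            upper_ext >= 1)
  direction_mix <- direction_mix / sum(direction_mix)
  structure(list(n_records = as.integer(n_records),
                 mirna_length = as.integer(mirna_length),
                 lower_stem_length = as.integer(lower_stem_length),
                 upper_ext = as.integer(upper_ext),
                 loop_length = as.integer(loop_length),
                 flank_length = as.integer(flank_length),
                 stem_identity = stem_identity,
                 duplex_identity = duplex_identity,
                 planted = planted,
                 direction_mix = direction_mix,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# counter-derived per-record seed, spread with a Lehmer step so nearby
# base seeds do not share record streams; stays below 2^31
record_seed <- function(base, i) {
  as.integer((as.numeric(base) * 48271 + i) %% 2147483629)
}

identity_kind <- function(id) {
  if (id %in% c("A-U", "G-C")) "WC"
  else if (id == "G-U") "WOBBLE"
  else if (id %in% MISMATCH_SYM) "MISMATCH"
  else "BULGE"
}

#' Generate one synthetic precursor with ground truth
#'
#' Samples a pair identity for every coordinate, emits the corresponding
#' nucleotides on the two arms (paired identities in random orientation,
#' bulges on the named arm with a gap opposite), assembles
#' flank + 5' arm + loop + 3' arm + flank, and returns the record with
#' its ground-truth dot-bracket together with the planted truth. The
#' basal flanks are A-rich and unstructured so that MFE folding engines
#' keep the planted hairpin. Deterministic per (spec, seed).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed for this record (defaults to `spec$seed`).
#' @return List with `record` (a [precursor_record()] with the truth
#'   structure attached) and `truth`: planted `classes` (data frame
#'   `coord`, `identity`, `kind`), `mirna_interval`, `star_interval`,
#'   `direction`.
#' @export
generate_precursor <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  L <- spec$mirna_length
  coords <- c(-(spec$lower_stem_length:1), seq_len(L + spec$upper_ext))
  ident <- character(length(coords))
  for (k in seq_along(coords)) {
    co <- coords[k]
    p <- spec$planted[[as.character(co)]]
    if (is.null(p)) p <- if (co < 0) spec$stem_identity else spec$duplex_identity
    ident[k] <- sample(names(p), 1L, prob = p)
  }

  # consolidate isolated base pairs: a lonely pair wedged between two
  # unpaired columns is energetically unstable and an MFE engine will not
  # reproduce it, so it is swapped with an adjacent unpaired column to
  # join the nearest helix. Swaps exchange whole identities between
  # coordinates drawn from the same distribution (marginals preserved)
  # and never move a coordinate with a planted override.
  # distribute the sampled unpaired columns evenly across the duplex
  # region: clustered mismatches open wide internal loops and isolated
  # base pairs that an MFE engine will not reproduce, so the drawn
  # identities are placed into slots by even spacing. This permutes
  # exchangeable draws from identical per-position distributions, so the
  # per-coordinate marginals are untouched; coordinates with planted
  # overrides are never moved.
  frozen <- coords %in% as.integer(names(spec$planted))
  is_paired_id <- function(id) identity_kind(id) %in% c("WC", "WOBBLE")
  slots <- which(coords > 0 & !frozen)
  vals <- ident[slots]
  unp <- vals[!vapply(vals, is_paired_id, logical(1))]
  prd <- vals[vapply(vals, is_paired_id, logical(1))]
  u <- length(unp); nsl <- length(slots)
  if (u > 0L && u < nsl) {
    # internal loops of at most two columns, separated by contiguous
    # helical runs of near-equal length
    n_groups <- ceiling(u / 2)
    p <- nsl - u
    run_len <- rep(p %/% (n_groups + 1L), n_groups + 1L)
    if (p %% (n_groups + 1L) > 0L)
      run_len[seq_len(p %% (n_groups + 1L))] <- run_len[1] + 1L
    group_len <- rep(2L, n_groups)
    if (u %% 2L == 1L) group_len[n_groups] <- 1L
    placed <- character(0)
    ui <- 1L; pi <- 1L
    for (gk in seq_len(n_groups)) {
      placed <- c(placed, prd[seq(pi, length.out = run_len[gk])],
                  unp[seq(ui, length.out = group_len[gk])])
      pi <- pi + run_len[gk]; ui <- ui + group_len[gk]
    }
    placed <- c(placed, prd[seq(pi, length.out = run_len[n_groups + 1L])])
    ident[slots] <- placed
  }

  # canonicalize unpaired runs to the registration convention: within a
  # maximal run of unpaired columns, mismatches sit nearest the duplex
  # anchor and bulges distal (stable within each kind), so that the
  # ground-truth class map is exactly what registration reconstructs
  kind0 <- vapply(ident, identity_kind, character(1))
  unpaired <- !kind0 %in% c("WC", "WOBBLE")
  run_id <- cumsum(c(TRUE, diff(unpaired) != 0 | diff(sign(coords)) != 0))
  for (r in unique(run_id[unpaired])) {
    idx <- which(run_id == r & unpaired)
    if (length(idx) < 2L) next
    is_bulge <- kind0[idx] == "BULGE"
    if (!any(is_bulge)) next
    ord <- if (coords[idx[1]] > 0) c(idx[!is_bulge], idx[is_bulge])
    else c(idx[is_bulge], idx[!is_bulge])
    ident[idx] <- ident[ord]
  }

  nt5 <- character(length(coords)); nt3 <- character(length(coords))
  for (k in seq_along(coords)) {
    id <- ident[k]
    if (id == "bulge5") {
      nt5[k] <- sample(NTS, 1L); nt3[k] <- NA_character_
    } else if (id == "bulge3") {
      nt5[k] <- NA_character_; nt3[k] <- sample(NTS, 1L)
    } else {
      pair <- strsplit(id, "-")[[1]]
      if (runif(1) < 0.5) pair <- rev(pair)
      nt5[k] <- pair[1]; nt3[k] <- pair[2]
    }
  }
  kind <- vapply(ident, identity_kind, character(1))
  paired <- kind %in% c("WC", "WOBBLE")

  # orient mismatch nucleotides to minimize spurious pairability with the
  # neighboring columns, so the planted helix stays the dominant fold
  pairable <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0L)
    as.integer(paste(sort(c(x, y)), collapse = "") %in% c("AU", "CG", "GU"))
  }
  slip_score <- function(k, a, b) {
    s <- 0L
    for (d in c(-1L, 1L)) {
      kk <- k + d
      if (kk < 1L || kk > length(coords)) next
      s <- s + pairable(a, nt3[kk]) + pairable(b, nt5[kk])
    }
    s
  }
  for (k in which(kind == "MISMATCH")) {
    fwd <- slip_score(k, nt5[k], nt3[k])
    rev_ <- slip_score(k, nt3[k], nt5[k])
    if (rev_ < fwd) {
      tmp <- nt5[k]; nt5[k] <- nt3[k]; nt3[k] <- tmp
    }
  }

  flank5 <- paste(sample(c("A", "A", "A", "C"), spec$flank_length,
                         replace = TRUE), collapse = "")
  flank3 <- paste(sample(c("A", "A", "A", "C"), spec$flank_length,
                         replace = TRUE), collapse = "")
  loop <- paste(c("G", rep("A", spec$loop_length - 1L)), collapse = "")

  arm5_idx <- which(!is.na(nt5))
  arm3_idx <- which(!is.na(nt3))
  arm5 <- paste(nt5[arm5_idx], collapse = "")
  arm3 <- paste(rev(nt3[arm3_idx]), collapse = "")
  sequence <- paste0(flank5, arm5, loop, arm3, flank3)

  # source positions per coordinate
  src5 <- rep(NA_integer_, length(coords))
  src5[arm5_idx] <- spec$flank_length + seq_along(arm5_idx)
  off3 <- spec$flank_length + nchar(arm5) + spec$loop_length
  src3 <- rep(NA_integer_, length(coords))
  # 3' arm written loop-outward: apical-most coordinate comes first
  src3[rev(arm3_idx)] <- off3 + seq_along(arm3_idx)

  db <- rep(".", nchar(sequence))
  db[src5[paired & !is.na(src5)]] <- "("
  db[src3[paired & !is.na(src3)]] <- ")"
  dotbracket <- paste(db, collapse = "")

  duplex <- coords >= 1 & coords <= L
  mirna_pos <- src5[duplex & !is.na(src5)]
  mirna_interval <- range(mirna_pos)
  star_cols <- coords >= -2 & coords <= L - 2
  star_pos <- src3[star_cols & !is.na(src3)]
  star_interval <- range(star_pos)

  direction <- sample(names(spec$direction_mix), 1L,
                      prob = spec$direction_mix)
  rec <- precursor_record(
    id = sprintf("syn_%08d", seed), sequence = sequence,
    mirna_start = mirna_interval[1], mirna_end = mirna_interval[2],
    arm = "5p", direction = direction,
    species = "synthetic", group = "synthetic", structure = dotbracket)
  truth <- list(classes = data.frame(coord = coords, identity = ident,
                                     kind = kind, stringsAsFactors = FALSE),
                mirna_interval = mirna_interval,
                star_interval = star_interval,
                direction = direction)
  list(record = rec, truth = truth)
}

#' Generate a synthetic survey on disk
#'
#' Writes `n_records` synthetic precursors through the package's own I/O
#' (FASTA, annotation TSV, dot-bracket file) plus a truth JSON recording
#' every planted class. Per-record seeds are derived from the spec seed
#' by counter through a multiplicative spreading step (so different spec
#' seeds yield disjoint record streams); the output is reproducible and
#' records are independent.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param basename File stem for the four outputs.
#' @return Invisible list with `records`, `truths` and `paths`.
#' @export
generate_survey <- function(spec, dir = tempfile("synsurvey"),
                            basename = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gens <- lapply(seq_len(spec$n_records), function(i)
    generate_precursor(spec, seed = record_seed(spec$seed, i)))
  records <- lapply(gens, `[[`, "record")
  truths <- lapply(gens, function(g) g$truth)
  ids <- vapply(records, `[[`, character(1), "id")
  names(truths) <- ids

  paths <- list(
    fasta = file.path(dir, paste0(basename, ".fa")),
    annotation = file.path(dir, paste0(basename, ".tsv")),
    dotbracket = file.path(dir, paste0(basename, ".db")),
    truth = file.path(dir, paste0(basename, "_truth.json")))
  seqs <- setNames(vapply(records, `[[`, character(1), "sequence"), ids)
  structs <- setNames(vapply(records, `[[`, character(1), "structure"), ids)
  write_fasta(seqs, paths$fasta)
  write_annotation_table(records, paths$annotation)
  write_dotbracket_file(structs, paths$dotbracket, sequences = seqs)
  jsonlite::write_json(
    lapply(truths, function(tr) list(
      classes = tr$classes, mirna_interval = tr$mirna_interval,
      star_interval = tr$star_interval, direction = tr$direction)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(records = records, truths = truths, paths = paths))
}
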