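WC_ORDERED <- c("A-U", "U-A", "G-C", "C-G")
WOBBLE_ORDERED <- c("G-U", "U-G")
NTS <- c("A", "C", "G", "U")
ORDERED_PAIRS <- as.vector(outer(NTS, NTS, paste, sep = "-"))
MISMATCH_SYM <- c("A-A", "C-C", "G-G", "U-U", "A-C", "A-G", "C-U")

#' Classify one registered position-pair
#'
#' Watson-Crick (A-U, G-C in either orientation), G-U wobble, mismatch
#' (two opposed unpaired nucleotides) or bulge (a nucleotide with no
#' counterpart). A position reported as paired by the structure but
#' carrying a non-canonical combination is an engine inconsistency and
#' raises an error.
#'
#' @param nt5,nt3 Nucleotides on the 5' and 3' arms (`NA` = gap).
#' @param paired Logical: are the two positions paired in the structure?
#' @param record_id Used in the integrity error message.
#' @return List with `kind` (`"WC"`, `"WOBBLE"`, `"MISMATCH"`,
#'   `"BULGE"`), `identity_ordered` (e.g. `"C-U"`, or `"bulge5"` /
#'   `"bulge3"` naming the arm carrying the extra nucleotide) and
#'   `identity_symmetric` (orientation-collapsed, e.g. `"G-C"`).
#' @export
classify_pair <- function(nt5, nt3, paired, record_id = NA_character_) {
  if (is.na(nt5) && is.na(nt3))
    stop("invalid position-pair: both sides are gaps")
  if (is.na(nt5) || is.na(nt3)) {
    side <- if (is.na(nt3)) "bulge5" else "bulge3"
    return(list(kind = "BULGE", identity_ordered = side,
                identity_symmetric = "bulge"))
  }
  ordered <- paste(nt5, nt3, sep = "-")
  symmetric <- paste(sort(c(nt5, nt3)), collapse = "-")
  if (symmetric == "C-G") symmetric <- "G-C"  # field-canonical label
  if (paired) {
    if (ordered %in% WC_ORDERED)
      return(list(kind = "WC", identity_ordered = ordered,
                  identity_symmetric = symmetric))
    if (ordered %in% WOBBLE_ORDERED)
      return(list(kind = "WOBBLE", identity_ordered = ordered,
                  identity_symmetric = "G-U"))
    stop("structure engine inconsistency: paired ", ordered,
         " in record ", record_id)
  }
  list(kind = "MISMATCH", identity_ordered = ordered,
       identity_symmetric = symmetric)
}

# vectorized classification of a duplex_alignment -> data.frame
classify_alignment <- function(aln) {
  cls <- lapply(seq_len(nrow(aln)), function(k)
    classify_pair(aln$nt5[k], aln$nt3[k], aln$paired[k],
                  attr(aln, "record_id")))
  data.frame(coord = aln$coord,
             kind = vapply(cls, `[[`, character(1), "kind"),
             ordered = vapply(cls, `[[`, character(1), "identity_ordered"),
             symmetric = vapply(cls, `[[`, character(1), "identity_symmetric"),
             stringsAsFactors = FALSE)
}

class_levels <- function(mode, include_bulge = TRUE) {
  lv <- switch(mode,
    kind = c("WC", "WOBBLE", "MISMATCH"),
    symmetric = c("A-U", "G-C", "G-U", MISMATCH_SYM),
    ordered = ORDERED_PAIRS,
    stop("unknown mode: ", mode))
  if (include_bulge)
    lv <- c(lv, if (mode == "ordered") c("bulge5", "bulge3") else "BULGE")
  lv
}

class_key <- function(cl, mode) {
  switch(mode,
    kind = ifelse(cl$kind == "BULGE", "BULGE", cl$kind),
    symmetric = ifelse(cl$kind == "BULGE", "BULGE", cl$symmetric),
    ordered = cl$ordered)
}

new_pair_freq_matrix <- function(values, counts, n_per_position, mode,
                                 n_precursors) {
  structure(list(values = values, counts = counts,
                 n_per_position = n_per_position, mode = mode,
                 n_precursors = n_precursors),
            class = "pair_freq_matrix")
}

#' @export
print.pair_freq_matrix <- function(x, ...) {
  cat(sprintf("<pair_freq_matrix> mode=%s, %d classes x %d positions, n=%s\n",
              x$mode, nrow(x$values), ncol(x$values),
              x$n_precursors %||% NA))
  print(round(x$values, 2))
  invisible(x)
}

#' Pooled pair-class composition over a window
#'
#' Pools every registered column whose coordinate falls in `window`
#' across all alignments (pooled counting, not per-precursor averaging)
#' and reports class percentages as a single column. In `kind` mode the
#' three classes are Watson-Crick, G-U wobble, and mismatch; with
#' `bulges = "unpaired"` (default for `kind`) bulged positions count as
#' mismatches so that WC + WOBBLE gives the paired share.
#'
#' @param alignments List of `duplex_alignment`s.
#' @param window Coordinates to pool; default every coordinate present.
#' @param mode `"kind"`, `"symmetric"` or `"ordered"`.
#' @param bulges `"own"` (separate class), `"unpaired"` (fold into
#'   MISMATCH; kind mode only), or `"exclude"`.
#' @return A [pair_freq_matrix] with one column `"overall"`.
#' @export
overall_composition <- function(alignments, window = NULL,
                                mode = c("kind", "symmetric", "ordered"),
                                bulges = NULL) {
  mode <- match.arg(mode)
  if (is.null(bulges)) bulges <- if (mode == "kind") "unpaired" else "own"
  bulges <- match.arg(bulges, c("own", "unpaired", "exclude"))
  if (length(alignments) == 0L) stop("no alignments supplied")
  cls <- do.call(rbind, lapply(alignments, classify_alignment))
  if (!is.null(window)) {
    if (length(intersect(cls$coord, window)) == 0L)
      stop("empty window: no registered coordinates fall in it")
    cls <- cls[cls$coord %in% window, , drop = FALSE]
  }
  keys <- class_key(cls, mode)
  if (bulges == "unpaired" && mode == "kind")
    keys[keys == "BULGE"] <- "MISMATCH"
  if (bulges == "exclude")
    keys <- keys[cls$kind != "BULGE"]
  lv <- class_levels(mode, include_bulge = bulges == "own")
  counts <- table(factor(keys, levels = lv))
  total <- sum(counts)
  vals <- matrix(100 * as.numeric(counts) / total, ncol = 1,
                 dimnames = list(lv, "overall"))
  cmat <- matrix(as.numeric(counts), ncol = 1,
                 dimnames = list(lv, "overall"))
  new_pair_freq_matrix(vals, cmat,
                       n_per_position = c(overall = total),
                       mode = mode, n_precursors = length(alignments))
}

#' Per-coordinate pair-class composition
#'
#' For each requested coordinate, the percentage of precursors showing
#' each pair class at that coordinate. Records whose alignment does not
#' reach a coordinate are excluded from that column's denominator, so
#' every column sums to 100.
#'
#' @param alignments List of `duplex_alignment`s.
#' @param coords Coordinates of interest; default the two DCL1 cleavage
#'   sites of a 21-nt miRNA: -1, 1, 2, 3 and 21-24.
#' @param mode `"symmetric"` (10 identities), `"ordered"` (16), or
#'   `"kind"`.
#' @param bulges `"own"` or `"exclude"`.
#' @return A [pair_freq_matrix], one column per coordinate.
#' @export
site_composition <- function(alignments,
                             coords = c(-1L, 1L, 2L, 3L, 21L, 22L, 23L, 24L),
                             mode = c("symmetric", "ordered", "kind"),
                             bulges = c("own", "exclude")) {
  mode <- match.arg(mode)
  bulges <- match.arg(bulges)
  lv <- class_levels(mode, include_bulge = bulges == "own")
  counts <- matrix(0, nrow = length(lv), ncol = length(coords),
                   dimnames = list(lv, as.character(coords)))
  npos <- setNames(integer(length(coords)), as.character(coords))
  for (aln in alignments) {
    cls <- classify_alignment(aln)
    for (ci in seq_along(coords)) {
      row <- cls[cls$coord == coords[ci], , drop = FALSE]
      if (nrow(row) == 0L) next
      if (bulges == "exclude" && row$kind[1] == "BULGE") next
      key <- class_key(row, mode)[1]
      counts[key, ci] <- counts[key, ci] + 1
      npos[ci] <- npos[ci] + 1L
    }
  }
  vals <- sweep(counts, 2, pmax(npos, 1L), "/") * 100
  vals[, npos == 0L] <- NA_real_
  new_pair_freq_matrix(vals, counts, npos, mode,
                       n_precursors = length(alignments))
}

#' Count mismatched positions across a set of alignments
#'
#' @param alignments List of `duplex_alignment`s.
#' @param window Coordinates to count over; default all.
#' @return List with `n_positions` (pooled mismatch-class positions;
#'   bulges are not mismatches) and `n_precursors` (alignments
#'   contributing at least one).
#' @export
count_mismatch_positions <- function(alignments, window = NULL) {
  per <- vapply(alignments, function(aln) {
    cls <- classify_alignment(aln)
    if (!is.null(window)) cls <- cls[cls$coord %in% window, , drop = FALSE]
    sum(cls$kind == "MISMATCH")
  }, numeric(1))
  list(n_positions = sum(per), n_precursors = sum(per > 0))
}

#' Nucleotide composition over registered positions
#'
#' Counts A/C/G/U over the non-gap nucleotides (both arms) of the given
#' coordinates, the input for the mononucleotide independence null.
#'
#' @param alignments List of `duplex_alignment`s.
#' @param window Coordinates to include; default all.
#' @return List with `counts`, `frequencies` (sum to 1) and `total`.
#' @export
nucleotide_composition <- function(alignments, window = NULL) {
  nts <- unlist(lapply(alignments, function(aln) {
    if (!is.null(window)) aln <- aln[aln$coord %in% window, , drop = FALSE]
    c(aln$nt5, aln$nt3)
  }))
  nts <- nts[!is.na(nts)]
  counts <- table(factor(nts, levels = NTS))
  list(counts = setNames(as.integer(counts), NTS),
       frequencies = setNames(as.numeric(counts) / sum(counts), NTS),
       total = sum(counts))
}

#' Expected pair frequencies under the mononucleotide independence null
#'
#' Under the null that the two nucleotides of a position-pair are drawn
#' independently from the mononucleotide composition, the expected share
#' of ordered pair (x, y) is p(x) * p(y); symmetric classes sum their
#' ordered members. When an observed matrix is supplied, per-class
#' log2(observed/expected) enrichments and a chi-square goodness-of-fit
#' statistic per position are added (zero-expected cells with nonzero
#' observed report `Inf` enrichment and are excluded from the chi-square
#' with a warning).
#'
#' @param composition Named frequency vector over A/C/G/U summing to 1
#'   (e.g. `nucleotide_composition(...)$frequencies`).
#' @param observed Optional [pair_freq_matrix] in `"ordered"` or
#'   `"symmetric"` mode.
#' @return List with `expected` (percent, named by class), and, given
#'   `observed`: `enrichment_log2` (classes x positions) and `chisq`
#'   (per-position statistic with `df`).
#' @export
expected_pair_frequencies <- function(composition, observed = NULL) {
  p <- composition[NTS]
  if (abs(sum(p) - 1) > 1e-9) stop("composition must sum to 1")
  exp_ordered <- setNames(as.vector(outer(p, p)) * 100, ORDERED_PAIRS)
  sym_of <- vapply(strsplit(ORDERED_PAIRS, "-"), function(x)
    paste(sort(x), collapse = "-"), character(1))
  exp_sym <- tapply(exp_ordered, sym_of, sum)
  out <- list(expected_ordered = exp_ordered,
              expected_symmetric = exp_sym[unique(sym_of)])
  if (is.null(observed)) return(out)

  if (!observed$mode %in% c("ordered", "symmetric"))
    stop("observed matrix must be in ordered or symmetric mode")
  expd <- if (observed$mode == "ordered") exp_ordered else out$expected_symmetric
  classes <- intersect(rownames(observed$values), names(expd))
  obs <- observed$values[classes, , drop = FALSE]
  cnt <- observed$counts[classes, , drop = FALSE]
  # renormalize over the compared class set (bulges etc. fall outside the null)
  obs <- sweep(obs, 2, colSums(obs), "/") * 100
  expv <- setNames(as.numeric(expd[classes]) /
                     sum(as.numeric(expd[classes])) * 100, classes)
  enr <- log2(sweep(obs, 1, expv, "/"))
  enr[obs == 0 & expv == 0] <- 0
  if (any(is.infinite(enr)))
    warning("zero expected with nonzero observed; Inf enrichment excluded ",
            "from chi-square")
  chisq <- apply(cnt, 2, function(k) {
    n <- sum(k)
    e <- expv / 100 * n
    ok <- e > 0
    sum((k[ok] - e[ok])^2 / e[ok])
  })
  out$expected <- expv
  out$enrichment_log2 <- enr
  out$chisq <- chisq
  out$df <- length(classes) - 1L
  out
}

#' Compare two pair-frequency matrices cell by cell
#'
#' Percentage-point differences with two-proportion z-tests (no
#' continuity correction), Benjamini-Hochberg adjusted across all cells.
#'
#' @param matrix_a,matrix_b [pair_freq_matrix] objects with identical
#'   class/coordinate layout and counts.
#' @return Data frame with columns `class`, `position`, `pct_a`,
#'   `pct_b`, `diff`, `p`, `p_adj`.
#' @export
compare_groups <- function(matrix_a, matrix_b) {
  if (!identical(dimnames(matrix_a$values), dimnames(matrix_b$values)))
    stop("matrix layouts differ; cannot compare")
  if (is.null(matrix_a$counts) || is.null(matrix_b$counts))
    stop("both matrices need counts for the z-test")
  grid <- expand.grid(class = rownames(matrix_a$values),
                      position = colnames(matrix_a$values),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    cl <- grid$class[k]; ps <- grid$position[k]
    ka <- matrix_a$counts[cl, ps]; kb <- matrix_b$counts[cl, ps]
    na <- matrix_a$n_per_position[[ps]]; nb <- matrix_b$n_per_position[[ps]]
    pa <- matrix_a$values[cl, ps]; pb <- matrix_b$values[cl, ps]
    p <- if (na > 0 && nb > 0 && (ka + kb) > 0 && (ka + kb) < (na + nb))
      suppressWarnings(prop.test(c(ka, kb), c(na, nb),
                                 correct = FALSE)$p.value)
    else 1
    data.frame(class = cl, position = ps, pct_a = pa, pct_b = pb,
               diff = pa - pb, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}

#' Count precursors carrying a given identity at a coordinate
#'
#' @param alignments List of `duplex_alignment`s.
#' @param coord Single coordinate.
#' @param identity Class label to match, in the chosen mode (e.g.
#'   `"C-C"`).
#' @param mode `"symmetric"`, `"ordered"` or `"kind"`.
#' @return List with `n_with` and `n_total` (alignments covering the
#'   coordinate).
#' @export
conservation_count <- function(alignments, coord, identity,
                               mode = c("symmetric", "ordered", "kind")) {
  mode <- match.arg(mode)
  hits <- 0L; total <- 0L
  for (aln in alignments) {
    row <- aln[aln$coord == coord, , drop = FALSE]
    if (nrow(row) == 0L) next
    total <- total + 1L
    cl <- classify_pair(row$nt5[1], row$nt3[1], row$paired[1])
    key <- switch(mode, kind = cl$kind, symmetric = cl$identity_symmetric,
                  ordered = cl$identity_ordered)
    if (key == identity) hits <- hits + 1L
  }
  list(n_with = hits, n_total = total)
}
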