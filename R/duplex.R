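#' Infer the miRNA* interval from the miRNA and the pairing table
#'
#' DCL1 cuts leave 2-nt 3' overhangs on both strands of the miRNA/miRNA*
#' duplex, so on the pairing table the star strand is anchored at
#' `partner(mirna_end - 2)` (star 5' end) and `partner(mirna_start) + 2`
#' (star 3' end). When an anchor position is unpaired in the fold, the
#' nearest paired position within 3 nt substitutes and the offset is
#' compensated, assuming locally helical geometry.
#'
#' @param struct A `secondary_structure` (or dot-bracket string).
#' @param mirna_interval Integer vector `c(start, end)`, 1-based
#'   inclusive.
#' @return Integer vector `c(start, end)` of the star interval, with
#'   attributes `clipped` (TRUE if truncated at a sequence end) and
#'   `interpolated` (TRUE if an unpaired anchor was compensated).
#' @export
infer_star <- function(struct, mirna_interval) {
  if (is.character(struct)) struct <- parse_dotbracket(struct)
  pt <- struct$pair_table
  n <- length(pt)
  interpolated <- FALSE

  # partner of pos, extrapolated along the local helix when pos is unpaired
  registered_partner <- function(pos) {
    for (d in c(0L, 1L, -1L, 2L, -2L, 3L, -3L)) {
      p <- pos + d
      if (p >= 1L && p <= n && pt[p] != 0L) {
        if (d != 0L) interpolated <<- TRUE
        return(pt[p] + d)
      }
    }
    NA_integer_
  }

  a5 <- registered_partner(mirna_interval[2] - 2L)
  a3 <- registered_partner(mirna_interval[1])
  if (is.na(a5) || is.na(a3))
    stop(structure(class = c("star_uninferrable", "error", "condition"),
                   list(message = "no paired anchor within 3 nt of a duplex end",
                        call = sys.call(-1))))
  ends <- sort(c(a5, a3 + if (a3 > a5) 2L else -2L))
  # a3 + 2 walks 2 nt toward the star 3' end, i.e. away from the loop
  star <- c(max(1L, ends[1]), min(n, ends[2]))
  attr(star, "clipped") <- !identical(star, ends)
  attr(star, "interpolated") <- interpolated
  star
}

GAP <- NA_character_

#' Register the two arms of a foldback into a duplex alignment
#'
#' A two-pointer walk anchored at the basal boundary of the miRNA/miRNA*
#' duplex pairs off the 5' arm (read 5'->3') against the 3' arm (read
#' 3'->5'). Positions paired with each other emit paired columns;
#' opposed unpaired positions emit mismatch columns; an unpaired position
#' whose counterpart is committed to a partner further along emits a
#' bulge column (gap on the far side). The walk extends below the duplex
#' (negative coordinates) and above it until the window, the terminal
#' loop, or a precursor end is exhausted. Within an internal loop,
#' mismatch columns sit nearest the anchor and bulges distal.
#'
#' @param struct A `secondary_structure` or dot-bracket string.
#' @param sequence The precursor sequence (RNA).
#' @param mirna_interval,star_interval 1-based inclusive intervals on
#'   opposite arms.
#' @param direction Processing direction, kept for labelling.
#' @param window Integer vector `c(below, above)`: maximum coordinates
#'   covered below (negative side) and at/above the basal anchor. The
#'   default 15 + 41 covers the documented 15-17 bp lower stem, the
#'   duplex and the region above it (56 columns; coordinate 0 does not
#'   exist).
#' @param record_id Identifier carried into the alignment.
#' @return A `duplex_alignment`: data frame with columns `coord`, `nt5`,
#'   `nt3`, `paired`, `src5`, `src3`, plus attributes `record_id`,
#'   `direction`, `duplex_span` and `truncated`.
#' @export
register_arms <- function(struct, sequence, mirna_interval, star_interval,
                          direction = "base_to_loop", window = c(15L, 41L),
                          record_id = NA_character_) {
  if (is.character(struct)) struct <- parse_dotbracket(struct)
  pt <- struct$pair_table
  sequence <- normalize_rna(sequence)
  n <- length(pt)
  if (nchar(sequence) != n)
    stop("sequence and structure lengths differ")
  iv <- list(mirna_interval, star_interval)
  if (max(iv[[1]][1], iv[[2]][1]) <= min(iv[[1]][2], iv[[2]][2]))
    stop("miRNA and star intervals overlap; cannot register")
  is5 <- if (mirna_interval[1] < star_interval[1]) 1L else 2L
  int5 <- iv[[is5]]; int3 <- iv[[3L - is5]]

  nt <- strsplit(sequence, "")[[1]]

  # basal anchor: coord 1 column holds the 5'-arm strand's basal end
  anchor5 <- int5[1]
  anchor3 <- NA_integer_
  if (pt[anchor5] != 0L && pt[anchor5] >= int3[1] && pt[anchor5] <= int3[2]) {
    anchor3 <- pt[anchor5]
  } else {
    for (d in c(1L, -1L, 2L, -2L, 3L, -3L)) {
      p <- anchor5 + d
      if (p >= 1L && p <= n && pt[p] != 0L && pt[p] > int5[2]) {
        anchor3 <- pt[p] + d
        break
      }
    }
    if (is.na(anchor3)) anchor3 <- int3[2] - 2L  # overhang geometry fallback
  }
  anchor3 <- min(max(anchor3, 1L), n)

  col <- function(i, j, paired) {
    list(nt5 = if (is.na(i)) GAP else nt[i],
         nt3 = if (is.na(j)) GAP else nt[j],
         paired = paired, src5 = i, src3 = j)
  }
  # partner of i lies ahead on the 3'-arm walk (between lo and j)?
  pending <- function(p, lo, hi) p != 0L && p >= lo && p <= hi

  up <- list()
  i <- anchor5; j <- anchor3
  while (length(up) < window[2] && i < j) {
    # stop at the terminal loop: no pairs left between the pointers
    remaining <- i:j
    if (!any(pt[remaining] != 0L & pt[remaining] >= i & pt[remaining] <= j))
      break
    if (pt[i] == j) {
      up[[length(up) + 1L]] <- col(i, j, TRUE); i <- i + 1L; j <- j - 1L
    } else if (pending(pt[i], i + 1L, j)) {
      up[[length(up) + 1L]] <- col(NA_integer_, j, FALSE); j <- j - 1L
    } else if (pending(pt[j], i, j - 1L)) {
      up[[length(up) + 1L]] <- col(i, NA_integer_, FALSE); i <- i + 1L
    } else {
      up[[length(up) + 1L]] <- col(i, j, FALSE); i <- i + 1L; j <- j - 1L
    }
  }

  down <- list()
  i <- anchor5 - 1L; j <- anchor3 + 1L
  while (length(down) < window[1] && i >= 1L && j <= n) {
    if (pt[i] == j) {
      down[[length(down) + 1L]] <- col(i, j, TRUE); i <- i - 1L; j <- j + 1L
    } else if (pending(pt[i], j + 1L, n)) {
      down[[length(down) + 1L]] <- col(NA_integer_, j, FALSE); j <- j + 1L
    } else if (pending(pt[j], 1L, i - 1L)) {
      down[[length(down) + 1L]] <- col(i, NA_integer_, FALSE); i <- i - 1L
    } else {
      down[[length(down) + 1L]] <- col(i, j, FALSE); i <- i - 1L; j <- j + 1L
    }
  }

  cols <- c(rev(down), up)
  coords <- c(if (length(down)) -(length(down):1L), seq_len(length(up)))
  aln <- data.frame(
    coord = coords,
    nt5 = vapply(cols, `[[`, character(1), "nt5"),
    nt3 = vapply(cols, `[[`, character(1), "nt3"),
    paired = vapply(cols, `[[`, logical(1), "paired"),
    src5 = vapply(cols, function(x) as.integer(x$src5 %||% NA), integer(1)),
    src3 = vapply(cols, function(x) as.integer(x$src3 %||% NA), integer(1)),
    stringsAsFactors = FALSE)

  in_duplex <- (!is.na(aln$src5) &
                  (aln$src5 >= int5[1] & aln$src5 <= int5[2])) |
    (!is.na(aln$src3) & (aln$src3 >= int3[1] & aln$src3 <= int3[2]))
  duplex_span <- if (any(in_duplex))
    range(aln$coord[in_duplex]) else c(NA_integer_, NA_integer_)

  structure(aln,
            class = c("duplex_alignment", "data.frame"),
            record_id = record_id,
            direction = direction,
            duplex_span = duplex_span,
            truncated = length(up) >= window[2] || length(down) >= window[1])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Label the two DCL1 cleavage sites on a registered alignment
#'
#' Coordinate 1 is fixed at the basal end of the miRNA/miRNA* duplex; the
#' basal cut spans coordinates -1, 1, 2, 3 and the apical cut L, L+1,
#' L+2, L+3 for an L-nt miRNA (21-24 for the canonical 21-mer). For
#' base-to-loop precursors the basal cut is the first cleavage site; for
#' loop-to-base precursors the site labels swap while the coordinates do
#' not. Unknown direction is treated as base-to-loop with a warning flag.
#'
#' @param alignment A `duplex_alignment`.
#' @param direction Processing direction; defaults to the alignment's.
#' @param mirna_length miRNA length L in nt (default 21).
#' @return The alignment with a `sites` attribute: list with `basal`,
#'   `apical`, `first`, `second` coordinate sets, `direction_used`, and
#'   `direction_assumed` (TRUE when unknown defaulted to base-to-loop).
#' @export
assign_cleavage_coords <- function(alignment,
                                   direction = attr(alignment, "direction"),
                                   mirna_length = 21L) {
  assumed <- FALSE
  if (is.null(direction) || is.na(direction) || direction == "unknown") {
    direction <- "base_to_loop"
    assumed <- TRUE
  }
  basal <- c(-1L, 1L, 2L, 3L)
  apical <- mirna_length + 0:3
  sites <- if (direction == "base_to_loop")
    list(basal = basal, apical = apical, first = basal, second = apical)
  else
    list(basal = basal, apical = apical, first = apical, second = basal)
  sites$direction_used <- direction
  sites$direction_assumed <- assumed
  attr(alignment, "sites") <- sites
  alignment
}

#' Register a whole record in one call
#'
#' Convenience wrapper: parses or folds the structure, checks the miRNA
#' placement, infers the star, registers the arms and labels the
#' cleavage sites.
#'
#' @param rec A [precursor_record()] (structure attached or foldable).
#' @param engine [engine_config()] used when the record lacks a
#'   structure.
#' @param window See [register_arms()].
#' @return A `duplex_alignment` with cleavage sites assigned, or an
#'   error/condition for quarantined records.
#' @export
register_duplex <- function(rec, engine = engine_config(),
                            window = c(15L, 41L)) {
  rec <- ensure_structure(rec, engine)
  reason <- validate_structure(rec)
  if (!is.null(reason))
    stop(structure(class = c("quarantine", "error", "condition"),
                   list(message = paste0(rec$id, ": ", reason), call = NULL)))
  struct <- parse_dotbracket(rec$structure)
  star <- infer_star(struct, rec$mirna_interval)
  aln <- register_arms(struct, rec$sequence, rec$mirna_interval,
                       c(star[1], star[2]), direction = rec$direction,
                       window = window, record_id = rec$id)
  assign_cleavage_coords(aln, rec$direction,
                         mirna_length = diff(rec$mirna_interval) + 1L)
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment> %s: %d columns, coords %d..%d\n",
              attr(x, "record_id") %||% "?", nrow(x),
              min(x$coord), max(x$coord)))
  span <- attr(x, "duplex_span")
  if (!any(is.na(span)))
    cat(sprintf("  duplex span %d..%d, direction %s\n",
                span[1], span[2], attr(x, "direction")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Write an alignment dump as TSV
#'
#' Columns `coord`, `nt5`, `nt3`, `paired`, `src5`, `src3`; gaps are
#' written as `-`.
#'
#' @param alignment A `duplex_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  df <- as.data.frame(alignment)
  df$nt5[is.na(df$nt5)] <- "-"
  df$nt3[is.na(df$nt3)] <- "-"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
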