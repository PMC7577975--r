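# Fixtures are built in code: small hairpins with known pairing, and an
# exhaustive registration oracle independent of the two-pointer walk.

# perfect hairpin: positions i and n+1-i paired for i <= stem, loop in
# the middle; returns dot-bracket
perfect_hairpin_db <- function(stem, loop = 4) {
  paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
}

# complementary stem sequence so that WC pairing is real
perfect_hairpin_seq <- function(stem, loop = 4) {
  fwd <- paste(rep(c("G", "C", "A", "U"), length.out = stem), collapse = "")
  rev_comp <- chartr("ACGU", "UGCA", paste(rev(strsplit(fwd, "")[[1]]),
                                           collapse = ""))
  paste0(fwd, strrep("A", loop), rev_comp)
}

# build a hairpin from an explicit basal-to-apical column plan:
# plan is a character vector over c("P" = paired, "M" = mismatch,
# "B5" = bulge on 5' arm, "B3" = bulge on 3' arm); returns list with
# sequence, dotbracket, pair table and per-column sources
planned_hairpin <- function(plan, loop = 4) {
  nt5 <- character(0); nt3 <- character(0)
  wc <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"))
  k <- 0
  for (ty in plan) {
    k <- k + 1
    if (ty == "P") {
      p <- wc[[(k %% 4) + 1]]
      nt5 <- c(nt5, p[1]); nt3 <- c(nt3, p[2])
    } else if (ty == "M") {
      nt5 <- c(nt5, "A"); nt3 <- c(nt3, "A")
    } else if (ty == "B5") {
      nt5 <- c(nt5, "C"); nt3 <- c(nt3, NA)
    } else if (ty == "B3") {
      nt5 <- c(nt5, NA); nt3 <- c(nt3, "C")
    } else stop("unknown column type ", ty)
  }
  i5 <- which(!is.na(nt5)); i3 <- which(!is.na(nt3))
  arm5 <- paste(nt5[i5], collapse = "")
  arm3 <- paste(rev(nt3[i3]), collapse = "")
  seqn <- paste0(arm5, strrep("A", loop), arm3)
  src5 <- rep(NA_integer_, length(plan)); src5[i5] <- seq_along(i5)
  src3 <- rep(NA_integer_, length(plan))
  src3[rev(i3)] <- nchar(arm5) + loop + seq_along(i3)
  db <- rep(".", nchar(seqn))
  paired_cols <- plan == "P"
  db[src5[paired_cols]] <- "("
  db[src3[paired_cols]] <- ")"
  list(sequence = seqn, dotbracket = paste(db, collapse = ""),
       src5 = src5, src3 = src3, plan = plan,
       n5 = length(i5), n3 = length(i3))
}

# Exhaustive oracle: enumerate every monotone registration of the region
# between pointers (i, j) that aligns each pair of the pair table,
# keep the minimum-gap alignments, break ties preferring mismatch over
# 5'-bulge over 3'-bulge at the column nearest the anchor. Written as
# plain recursion; completely independent of register_arms().
oracle_walk_up <- function(pt, i, j) {
  pending <- function(p, lo, hi) p != 0 && p >= lo && p <= hi
  rank_of <- c(P = 0, M = 0, B5 = 1, B3 = 2)
  enum <- function(i, j) {
    if (i >= j) return(list(list()))
    rem <- i:j
    if (!any(pt[rem] != 0 & pt[rem] >= i & pt[rem] <= j))
      return(list(list()))
    prepend <- function(colm, rest) lapply(rest, function(r) c(list(colm), r))
    i <- as.integer(i); j <- as.integer(j)
    if (pt[i] == j)
      return(prepend(list(type = "P", i = i, j = j), enum(i + 1L, j - 1L)))
    pi_pend <- pending(pt[i], i + 1L, j)
    pj_pend <- pending(pt[j], i, j - 1L)
    if (pi_pend && pj_pend) stop("crossing pairs; not a nested structure")
    if (pi_pend)
      return(prepend(list(type = "B3", i = NA_integer_, j = j),
                     enum(i, j - 1L)))
    if (pj_pend)
      return(prepend(list(type = "B5", i = i, j = NA_integer_),
                     enum(i + 1L, j)))
    c(prepend(list(type = "M", i = i, j = j), enum(i + 1L, j - 1L)),
      prepend(list(type = "B5", i = i, j = NA_integer_), enum(i + 1L, j)),
      prepend(list(type = "B3", i = NA_integer_, j = j), enum(i, j - 1L)))
  }
  alns <- enum(i, j)
  gaps <- vapply(alns, function(a)
    sum(vapply(a, function(co) co$type %in% c("B5", "B3"), logical(1))),
    numeric(1))
  alns <- alns[gaps == min(gaps)]
  keys <- vapply(alns, function(a)
    paste(sprintf("%d", rank_of[vapply(a, `[[`, character(1), "type")]),
          collapse = ""), character(1))
  alns[[order(keys)[1]]]
}

# convert a register_arms() result (coords >= 1) to the oracle's shape
alignment_to_cols <- function(aln) {
  up <- aln[aln$coord >= 1, , drop = FALSE]
  lapply(seq_len(nrow(up)), function(k) {
    ty <- if (up$paired[k]) "P"
    else if (is.na(up$src3[k])) "B5"
    else if (is.na(up$src5[k])) "B3"
    else "M"
    list(type = ty, i = up$src5[k], j = up$src3[k])
  })
}

# all plans of a given length with at most `max_bulges` per arm, paired
# ends (anchored helices) -- small instance space for the oracle test
bulge_plans <- function(len, max_bulges = 2) {
  types <- c("P", "M", "B5", "B3")
  grid <- do.call(expand.grid,
                  c(rep(list(types), len - 2), stringsAsFactors = FALSE))
  plans <- lapply(seq_len(nrow(grid)), function(r)
    c("P", as.character(grid[r, ]), "P"))
  keep <- vapply(plans, function(p)
    sum(p == "B5") <= max_bulges && sum(p == "B3") <= max_bulges,
    logical(1))
  plans[keep]
}

syn_quick <- function(n = 20, seed = 42, ...) {
  synthetic_spec(n_records = n, seed = seed, ...)
}

register_generated <- function(gen) {
  register_duplex(gen$record, engine = list(available = FALSE))
}
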