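#' Parse a dot-bracket string into a secondary structure
#'
#' Bracket matching is done with a stack; positions are 1-based. The
#' resulting pair table is an involution: `pair_table[pair_table[i]] == i`
#' for every paired `i`, and `pair_table[i] == 0` marks unpaired
#' positions. Pseudoknots are not expressible in plain dot-bracket and are
#' therefore impossible here.
#'
#' @param s String over `(`, `)`, `.`.
#' @param mfe Optional free energy (kcal/mol) to attach.
#' @return An object of class `secondary_structure` with fields
#'   `dotbracket`, `pair_table`, `mfe`.
#' @export
parse_dotbracket <- function(s, mfe = NULL) {
  s <- as.character(s)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("invalid character '%s' at index %d", chars[bad[1]], bad[1]))
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L)
        stop(sprintf("unbalanced ')' at index %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced '(' at index %d (unclosed)", stack[1]))
  structure(list(dotbracket = s, pair_table = pt, mfe = mfe),
            class = "secondary_structure")
}

#' Render a secondary structure back to its dot-bracket string
#'
#' @param struct A `secondary_structure`.
#' @return The dot-bracket string; `parse_dotbracket(render_dotbracket(x))`
#'   reproduces `x`.
#' @export
render_dotbracket <- function(struct) {
  pt <- struct$pair_table
  chars <- rep(".", length(pt))
  paired <- which(pt != 0)
  chars[paired[pt[paired] > paired]] <- "("
  chars[paired[pt[paired] < paired]] <- ")"
  paste(chars, collapse = "")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs%s\n",
              nchar(x$dotbracket), sum(x$pair_table != 0) / 2,
              if (is.null(x$mfe)) "" else sprintf(", MFE %.2f kcal/mol", x$mfe)))
  cat(" ", x$dotbracket, "\n")
  invisible(x)
}

# in-memory fold cache, keyed by sequence + engine signature
.fold_cache <- new.env(parent = emptyenv())

#' Default folding-engine configuration
#'
#' The engine is ViennaRNA's `RNAfold` run at default parameters,
#' returning the single minimum-free-energy structure. Engine name and
#' version are stamped into survey reports for provenance.
#'
#' @param command Engine executable (must accept sequences on stdin and
#'   print `sequence\\nstructure (energy)`).
#' @param args Extra command-line arguments.
#' @return List with `command`, `args`, and the reported `version`
#'   (NA when the engine is unavailable).
#' @export
engine_config <- function(command = "RNAfold", args = c("--noPS")) {
  path <- Sys.which(command)
  version <- NA_character_
  if (nzchar(path)) {
    version <- tryCatch(
      trimws(system2(command, "--version", stdout = TRUE, stderr = TRUE)[1]),
      error = function(e) NA_character_)
  }
  list(command = command, args = args, version = version,
       available = nzchar(path))
}

#' Fold a sequence with the configured MFE engine
#'
#' Deterministic for a fixed engine and parameters; results are cached in
#' memory keyed by (sequence, engine, args).
#'
#' @param sequence RNA string (A/C/G/U).
#' @param engine An [engine_config()].
#' @return A `secondary_structure` with the engine's MFE estimate.
#' @export
fold_sequence <- function(sequence, engine = engine_config()) {
  sequence <- normalize_rna(sequence)
  if (grepl("[^ACGU]", sequence))
    stop("fold_sequence() requires a pure A/C/G/U sequence")
  if (!isTRUE(engine$available))
    stop("folding engine '", engine$command, "' not found on PATH; ",
         "supply precomputed dot-bracket structures instead ",
         "(see read_dotbracket_file())")
  key <- paste(engine$command, paste(engine$args, collapse = " "),
               sequence, sep = "|")
  if (!is.null(.fold_cache[[key]])) return(.fold_cache[[key]])
  out <- system2(engine$command, engine$args, input = sequence,
                 stdout = TRUE, stderr = FALSE)
  st <- attr(out, "status")
  if (!is.null(st) && st != 0L)
    stop("folding engine failed (exit ", st, ") on a ",
         nchar(sequence), "-nt sequence")
  line <- out[grepl("^[().]+\\s*\\(", out) | grepl("^[().]+$", out)][1]
  if (is.na(line)) stop("could not parse engine output")
  db <- sub("\\s.*$", "", line)
  mfe <- suppressWarnings(as.numeric(
    sub("^.*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", line)))
  res <- parse_dotbracket(db, mfe = if (is.na(mfe)) NULL else mfe)
  .fold_cache[[key]] <- res
  res
}

#' Attach a structure to a record, folding if necessary
#'
#' @param rec A [precursor_record()].
#' @param engine An [engine_config()]; only used when the record carries
#'   no precomputed structure.
#' @return The record with its `structure` field filled.
#' @export
ensure_structure <- function(rec, engine = engine_config()) {
  if (is.null(rec$structure))
    rec$structure <- fold_sequence(rec$sequence, engine)$dotbracket
  rec
}

#' Check that a record's miRNA lies on a single arm
#'
#' A usable record has its miRNA inside one helix arm of the foldback:
#' every paired miRNA position must have its partner outside the miRNA
#' interval. Records whose miRNA spans the terminal loop apex (a partner
#' inside the interval) are quarantined as `mirna_spans_loop`; records
#' whose miRNA is entirely unpaired as `mirna_unstructured`.
#'
#' @param rec A [precursor_record()] with a structure attached.
#' @return `NULL` if the record passes, else the quarantine reason.
#' @export
validate_structure <- function(rec) {
  if (is.null(rec$structure)) stop("record has no structure: ", rec$id)
  pt <- parse_dotbracket(rec$structure)$pair_table
  idx <- rec$mirna_interval[1]:rec$mirna_interval[2]
  partners <- pt[idx]
  paired <- partners != 0
  if (!any(paired)) return("mirna_unstructured")
  if (any(partners[paired] %in% idx)) return("mirna_spans_loop")
  NULL
}
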