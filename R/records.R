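#' Annotated precursor record
#'
#' A `precursor_record` bundles one precursor sequence with the annotation
#' needed to place its miRNA: the mature miRNA interval (1-based,
#' inclusive), the arm carrying it, and the DCL1 processing direction.
#'
#' @param id Record identifier (first whitespace-delimited FASTA token).
#' @param sequence Precursor sequence; DNA is accepted and transcribed
#'   (`T` becomes `U`), case is normalized to upper.
#' @param mirna_start,mirna_end 1-based inclusive coordinates of the mature
#'   miRNA on the precursor.
#' @param arm `"5p"` or `"3p"`.
#' @param direction Processing direction: `"base_to_loop"`,
#'   `"loop_to_base"`, or `"unknown"`.
#' @param species,group Free-text species name and taxon bucket (e.g.
#'   `"arabidopsis"`, `"eudicot"`, `"human"`).
#' @param structure Optional dot-bracket string, same length as the
#'   sequence.
#' @return An object of class `precursor_record`.
#' @export
precursor_record <- function(id, sequence, mirna_start, mirna_end,
                             arm = c("5p", "3p"),
                             direction = c("base_to_loop", "loop_to_base",
                                           "unknown"),
                             species = NA_character_, group = NA_character_,
                             structure = NULL) {
  arm <- match.arg(arm)
  direction <- match.arg(direction)
  rec <- structure(
    list(id = as.character(id),
         species = as.character(species),
         group = as.character(group),
         sequence = normalize_rna(sequence),
         mirna_interval = c(as.integer(mirna_start), as.integer(mirna_end)),
         arm = arm,
         direction = direction,
         structure = if (is.null(structure)) NULL else as.character(structure)),
    class = "precursor_record")
  rec
}

#' @export
print.precursor_record <- function(x, ...) {
  cat(sprintf("<precursor_record> %s (%s, %s)\n", x$id,
              ifelse(is.na(x$group), "ungrouped", x$group), x$arm))
  cat(sprintf("  %d nt, miRNA [%d, %d], direction %s, structure %s\n",
              nchar(x$sequence), x$mirna_interval[1], x$mirna_interval[2],
              x$direction, if (is.null(x$structure)) "absent" else "present"))
  invisible(x)
}

# Uppercase, transcribe T->U. Does not validate the alphabet; that is the
# job of validate_record() so that bad records are quarantined, not lost.
normalize_rna <- function(x) {
  chartr("T", "U", toupper(as.character(x)))
}

#' Validate a precursor record
#'
#' Checks the record invariants: pure A/C/G/U alphabet, miRNA coordinates
#' inside the sequence, miRNA length within 19-25 nt, and (when a
#' structure is attached) equal sequence/structure lengths. Returns `NULL`
#' for a valid record, otherwise a single string naming the violated
#' invariant -- callers quarantine on that reason rather than dropping the
#' record silently.
#'
#' @param rec A [precursor_record()].
#' @return `NULL` if valid, else a reason string.
#' @export
validate_record <- function(rec) {
  if (grepl("[^ACGU]", rec$sequence)) return("non_acgu_alphabet")
  s <- rec$mirna_interval[1]; e <- rec$mirna_interval[2]
  if (is.na(s) || is.na(e) || s < 1 || e < s || e > nchar(rec$sequence))
    return("coordinate_out_of_range")
  len <- e - s + 1
  if (len < 19 || len > 25) return("mirna_length_out_of_range")
  if (!is.null(rec$structure) &&
      nchar(rec$structure) != nchar(rec$sequence))
    return("structure_length_mismatch")
  NULL
}

#' Partition records into valid and quarantined sets
#'
#' Applies [validate_record()] to each record. Every input record ends up
#' in exactly one of the two buckets (`records_in == valid + quarantined`).
#'
#' @param records List of [precursor_record()] objects.
#' @return List with elements `valid` (list of records) and `quarantine`
#'   (data frame with columns `id`, `reason`).
#' @export
validate_records <- function(records) {
  reasons <- vapply(records, function(r) {
    v <- validate_record(r)
    if (is.null(v)) NA_character_ else v
  }, character(1))
  bad <- !is.na(reasons)
  list(valid = records[!bad],
       quarantine = data.frame(
         id = vapply(records[bad], `[[`, character(1), "id"),
         reason = reasons[bad],
         stringsAsFactors = FALSE))
}
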