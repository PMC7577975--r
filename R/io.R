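#' Read a FASTA file of precursor sequences
#'
#' Sequences are uppercased and transcribed to the RNA alphabet (T -> U).
#' IDs are the first whitespace-delimited token of each header. Records
#' containing characters outside A/C/G/U are returned as-is; downstream
#' validation quarantines them.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = ids), in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header",
                 nonempty[1], path))
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_rna(as.character(set))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  setNames(unname(seqs), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

annotation_columns <- c("id", "species", "group", "mirna_start",
                        "mirna_end", "arm", "direction")

#' Read an annotation table and join it to sequences
#'
#' The table is tab-delimited with a header row and columns `id`,
#' `species`, `group`, `mirna_start`, `mirna_end`, `arm`, `direction`
#' (blank direction means unknown). Each row is joined to a FASTA record
#' by `id`; rows violating the record invariants are quarantined with a
#' reason, never dropped silently.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Named character vector as from [read_fasta()], or a
#'   path to a FASTA file.
#' @param structures Optional named character vector of dot-bracket
#'   strings (or path to a dot-bracket file) attached to records by id.
#' @return List of valid [precursor_record()]s, with a `quarantine`
#'   attribute (data frame `id`, `reason`).
#' @export
read_annotation_table <- function(path, sequences, structures = NULL) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences) && is.null(names(sequences)))
    sequences <- read_fasta(sequences)
  if (is.character(structures) && length(structures) == 1L &&
      file.exists(structures) && is.null(names(structures)))
    structures <- read_dotbracket_file(structures)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  missing_cols <- setdiff(annotation_columns, names(tab))
  if (length(missing_cols))
    stop("annotation table missing columns: ",
         paste(missing_cols, collapse = ", "))
  orphans <- setdiff(tab$id, names(sequences))
  if (length(orphans))
    stop("annotation ids with no sequence: ",
         paste(orphans, collapse = ", "))

  records <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    dir <- row$direction
    if (is.na(dir) || !nzchar(dir)) dir <- "unknown"
    st <- if (!is.null(structures) && row$id %in% names(structures))
      structures[[row$id]] else NULL
    records[[k]] <- precursor_record(
      id = row$id, sequence = sequences[[row$id]],
      mirna_start = suppressWarnings(as.integer(row$mirna_start)),
      mirna_end = suppressWarnings(as.integer(row$mirna_end)),
      arm = row$arm, direction = dir,
      species = row$species, group = row$group, structure = st)
  }
  split <- validate_records(records)
  structure(split$valid, quarantine = split$quarantine)
}

#' Write an annotation table for a list of records
#'
#' @param records List of [precursor_record()]s.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(records, path) {
  tab <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    species = vapply(records, `[[`, character(1), "species"),
    group = vapply(records, `[[`, character(1), "group"),
    mirna_start = vapply(records, function(r) r$mirna_interval[1], integer(1)),
    mirna_end = vapply(records, function(r) r$mirna_interval[2], integer(1)),
    arm = vapply(records, `[[`, character(1), "arm"),
    direction = vapply(records, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Vienna dot-bracket file
#'
#' Accepts the common dialects: blocks of `>id`, optional sequence line,
#' then a structure line (possibly with a trailing ` (-12.30)` energy).
#'
#' @param path Path to the file.
#' @return Named character vector of dot-bracket strings.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  id <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "\\s+")[[1]][1]
    } else {
      body <- sub("\\s*\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", ln)
      if (grepl("^[().]+$", body)) {
        if (is.null(id)) stop("structure line before any '>' header in ", path)
        out[id] <- body
      }
      # sequence lines are ignored; ids come from headers
    }
  }
  out
}

#' Write structures as a Vienna dot-bracket file
#'
#' @param structures Named character vector of dot-bracket strings.
#' @param path Output path.
#' @param sequences Optional named character vector; when supplied, each
#'   block carries the sequence line above the structure line.
#' @return `path`, invisibly.
#' @export
write_dotbracket_file <- function(structures, path, sequences = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(structures)) {
    writeLines(paste0(">", id), con)
    if (!is.null(sequences) && id %in% names(sequences))
      writeLines(sequences[[id]], con)
    writeLines(structures[[id]], con)
  }
  invisible(path)
}

#' Serialize a pair-frequency matrix
#'
#' TSV layout: classes as rows, positions as columns, percentages to two
#' decimals, with `n` per position as a final `#n` comment row. JSON
#' carries full precision plus a metadata block.
#'
#' @param mat A [pair_freq_matrix] as returned by [site_composition()] or
#'   [overall_composition()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param metadata Optional named list merged into the JSON metadata
#'   block.
#' @return `path`, invisibly.
#' @export
write_frequency_report <- function(mat, path, format = c("tsv", "json"),
                                   metadata = list()) {
  format <- match.arg(format)
  stopifnot(inherits(mat, "pair_freq_matrix"))
  colsum <- colSums(mat$values)
  if (any(abs(colsum - 100) > 0.01))
    stop("frequency columns must sum to 100 (max deviation ",
         format(max(abs(colsum - 100))), ")")
  if (format == "tsv") {
    out <- rbind(
      format(round(mat$values, 2), nsmall = 2, trim = TRUE),
      `#n` = as.character(mat$n_per_position))
    df <- data.frame(class = rownames(out), out, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("class", colnames(mat$values))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- list(
      metadata = c(list(n_precursors = mat$n_precursors,
                        n_positions = ncol(mat$values),
                        mode = mat$mode), metadata),
      positions = colnames(mat$values),
      classes = rownames(mat$values),
      n_per_position = mat$n_per_position,
      counts = mat$counts,
      values = mat$values)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(path)
}

#' Read back a serialized pair-frequency matrix
#'
#' Inverse of [write_frequency_report()]; the JSON route is a full-
#' precision round trip, the TSV route round-trips values at two decimals.
#'
#' @param path Path written by [write_frequency_report()].
#' @param format `"tsv"` or `"json"`; guessed from the extension by
#'   default.
#' @return A [pair_freq_matrix].
#' @export
read_frequency_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = "character")
    nrow_idx <- df$class == "#n"
    npos <- as.integer(df[nrow_idx, -1])
    vals <- as.matrix(df[!nrow_idx, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- df$class[!nrow_idx]
    new_pair_freq_matrix(values = vals, counts = NULL,
                         n_per_position = setNames(npos, colnames(vals)),
                         mode = "unknown", n_precursors = NA_integer_)
  } else {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    vals <- matrix(p$values, nrow = length(p$classes),
                   dimnames = list(p$classes, p$positions), byrow = FALSE)
    cnts <- if (!is.null(p$counts))
      matrix(p$counts, nrow = length(p$classes),
             dimnames = list(p$classes, p$positions)) else NULL
    new_pair_freq_matrix(values = vals, counts = cnts,
                         n_per_position = setNames(as.integer(p$n_per_position),
                                                   p$positions),
                         mode = p$metadata$mode,
                         n_precursors = p$metadata$n_precursors)
  }
}

#' Convert miRBase-style hairpin + mature FASTA files to precursor records
#'
#' Each mature sequence is located in its hairpin by exact substring
#' search (sequences normalized to RNA). Matures whose hairpin id is not
#' the prefix of the mature id are matched by scanning all hairpins.
#' Ambiguous (multiple hits within one hairpin) or absent matches are
#' quarantined. The arm is called by comparing the mature midpoint to the
#' hairpin midpoint; the processing direction is left unknown.
#'
#' @param hairpins Named character vector of hairpin sequences or a FASTA
#'   path.
#' @param matures Named character vector of mature sequences or a FASTA
#'   path.
#' @param group Group label stamped on every record (default `"human"`,
#'   the typical use).
#' @param species Species label for the records.
#' @return List of valid [precursor_record()]s with a `quarantine`
#'   attribute.
#' @export
mirbase_convert <- function(hairpins, matures, group = "human",
                            species = NA_character_) {
  if (is.character(hairpins) && length(hairpins) == 1L && is.null(names(hairpins)))
    hairpins <- read_fasta(hairpins)
  if (is.character(matures) && length(matures) == 1L && is.null(names(matures)))
    matures <- read_fasta(matures)
  hairpins <- setNames(normalize_rna(hairpins), names(hairpins))
  matures <- setNames(normalize_rna(matures), names(matures))

  quarantine <- data.frame(id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  records <- list()
  for (mid in names(matures)) {
    # miRBase mature ids extend the hairpin id (e.g. hsa-mir-21 -> hsa-miR-21-5p)
    stem <- tolower(sub("-(5p|3p)$", "", mid))
    stem <- gsub("mir", "mir", stem, ignore.case = TRUE)
    cand <- names(hairpins)[tolower(names(hairpins)) == stem]
    if (length(cand) == 0L)
      cand <- names(hairpins)[vapply(hairpins, function(h)
        grepl(matures[[mid]], h, fixed = TRUE), logical(1))]
    if (length(cand) == 0L) {
      quarantine <- rbind(quarantine,
                          data.frame(id = mid, reason = "no_hairpin_match"))
      next
    }
    if (length(cand) > 1L) {
      quarantine <- rbind(quarantine,
                          data.frame(id = mid, reason = "ambiguous_hairpin"))
      next
    }
    h <- hairpins[[cand]]
    hits <- gregexpr(matures[[mid]], h, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      quarantine <- rbind(quarantine,
                          data.frame(id = mid, reason = "mature_not_in_hairpin"))
      next
    }
    if (length(hits) > 1L) {
      quarantine <- rbind(quarantine,
                          data.frame(id = mid, reason = "ambiguous_substring"))
      next
    }
    s <- as.integer(hits[1]); e <- s + nchar(matures[[mid]]) - 1L
    arm <- if ((s + e) / 2 <= (nchar(h) + 1) / 2) "5p" else "3p"
    records[[length(records) + 1L]] <- precursor_record(
      id = mid, sequence = h, mirna_start = s, mirna_end = e,
      arm = arm, direction = "unknown", species = species, group = group)
  }
  split <- validate_records(records)
  structure(split$valid,
            quarantine = rbind(quarantine, split$quarantine))
}
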