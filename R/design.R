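#' Default amiRNA design ruleset
#'
#' The rules distil the survey's empirical outcomes into a screening
#' scheme for artificial miRNA precursors. Identities with a more than
#' ten-fold loss of mature miRNA in mutagenesis are `fail`; roughly
#' two-fold or context-dependent effects are `warn`:
#'
#' * **R1 (fail)** C-C mismatch anywhere in the registered window: C-C
#'   consistently impairs biogenesis and is essentially absent from
#'   natural cleavage sites.
#' * **R2 (fail)** G-G mismatch at a cleavage-site coordinate.
#' * **R3 (warn)** G-G mismatch elsewhere (rare in natural precursors).
#' * **R4 (warn)** any mismatch identity outside A-C, U-C, U-U at a
#'   cleavage-site coordinate (A-A, A-G, G-A variants retain only ~10%
#'   mature miRNA).
#' * **R5 (warn)** unpaired at coordinates 1, 3 or L+2 (position 23 for a
#'   21-mer), which are paired in most natural precursors.
#' * **R6 (info)** C-C inside the miRNA/miRNA* duplex additionally
#'   flags possible isomiR generation (processing variants), a
#'   qualitative effect.
#'
#' Position -1 being unpaired is never penalized: about 40% of natural
#' precursors are unpaired there.
#'
#' @param enabled Character vector of rule ids to activate.
#' @return Character vector of active rule ids.
#' @export
amirna_rules <- function(enabled = c("R1", "R2", "R3", "R4", "R5", "R6")) {
  match.arg(enabled, c("R1", "R2", "R3", "R4", "R5", "R6"),
            several.ok = TRUE)
}

ALLOWED_MISMATCHES <- c("A-C", "C-U", "U-U")  # symmetric identities

#' Screen a registered precursor against the amiRNA design rules
#'
#' @param alignment A `duplex_alignment` with cleavage sites assigned
#'   (see [register_duplex()]); unregistered input is an error.
#' @param rules Active rule ids, see [amirna_rules()].
#' @return A `design_report`: list with `record_id`, `findings` (data
#'   frame `rule_id`, `coord`, `observed`, `severity`, `citation`) and
#'   `verdict` (`"pass"`, `"warn"` or `"fail"`).
#' @export
amirna_check <- function(alignment, rules = amirna_rules()) {
  if (!inherits(alignment, "duplex_alignment") ||
      is.null(attr(alignment, "sites")))
    stop("input is not a registered alignment; run register_duplex() first")
  sites <- attr(alignment, "sites")
  site_coords <- c(sites$basal, sites$apical)
  span <- attr(alignment, "duplex_span")
  cls <- classify_alignment(alignment)

  findings <- list()
  add <- function(rule, coord, observed, severity, citation) {
    findings[[length(findings) + 1L]] <<- data.frame(
      rule_id = rule, coord = coord, observed = observed,
      severity = severity, citation = citation, stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(cls))) {
    co <- cls$coord[k]; kind <- cls$kind[k]; idy <- cls$symmetric[k]
    at_site <- co %in% site_coords
    if (kind == "MISMATCH") {
      if (idy == "C-C") {
        if ("R1" %in% rules)
          add("R1", co, "C-C mismatch", "fail",
              "C-C mismatches consistently impair miRNA biogenesis")
        if ("R6" %in% rules && !any(is.na(span)) &&
            co >= span[1] && co <= span[2])
          add("R6", co, "C-C in miRNA/miRNA* duplex", "info",
              "C-C within the duplex can trigger isomiR generation")
      } else if (idy == "G-G") {
        if (at_site && "R2" %in% rules)
          add("R2", co, "G-G mismatch at cleavage site", "fail",
              "G-G at DCL1 cleavage sites strongly reduces processing")
        else if (!at_site && "R3" %in% rules)
          add("R3", co, "G-G mismatch", "warn",
              "G-G mismatches are rare in natural precursors")
      } else if (at_site && !idy %in% ALLOWED_MISMATCHES &&
                 "R4" %in% rules) {
        add("R4", co, paste0(idy, " mismatch at cleavage site"), "warn",
            "only A-C, U-C and U-U mismatches are well tolerated at cleavage sites")
      }
    }
    # paired-position rule: coordinates 1, 3 and L+2 are mostly paired
    mostly_paired <- c(1L, 3L, sites$apical[3])
    if ("R5" %in% rules && co %in% mostly_paired && kind %in%
        c("MISMATCH", "BULGE") && co != -1L)
      add("R5", co, paste0("unpaired (", cls$ordered[k], ")"), "warn",
          "positions 1, 3 and 23 are paired in most natural precursors")
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(rule_id = character(0), coord = integer(0),
               observed = character(0), severity = character(0),
               citation = character(0), stringsAsFactors = FALSE)
  verdict <- if (any(findings$severity == "fail")) "fail"
  else if (any(findings$severity == "warn")) "warn"
  else "pass"
  structure(list(record_id = attr(alignment, "record_id"),
                 findings = findings, verdict = verdict),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s: %s (%d findings)\n",
              x$record_id %||% "?", toupper(x$verdict), nrow(x$findings)))
  if (nrow(x$findings)) print.data.frame(x$findings, row.names = FALSE)
  invisible(x)
}

#' Serialize a design report
#'
#' @param report A `design_report`.
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(record_id = report$record_id,
                              verdict = report$verdict,
                              findings = report$findings),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
  }
  invisible(path)
}
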