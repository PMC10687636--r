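#' Curate peptide records: remove redundant, incomplete and
#' cysteine-deficient sequences
#'
#' Applies, in order and per record: exact-duplicate residue strings after
#' the first occurrence are rejected (\code{redundant}); sequences carrying
#' ambiguity or non-standard codes (X, B, Z, J, U, O) or a stop character
#' (*) are rejected (\code{incomplete}); sequences with fewer than
#' \code{min_cys} cysteines are rejected (\code{cysteine_pattern}).
#' Rejections are reported, never raised. The result is deterministic in
#' input order: among duplicates, the first wins.
#'
#' @param records peptide record data frame.
#' @param min_cys minimum cysteine count; defaults to 5, the anchor count of
#'   the scaffold motif.
#' @return list of class \code{curation_report} with elements \code{kept}
#'   (peptide records) and \code{rejected} (data frame of \code{id},
#'   \code{reason}).
#' @export
curate <- function(records, min_cys = 5L) {
  records <- as_peptide_records(records)
  if (nrow(records) == 0L) stop("no records to curate")
  stopifnot(min_cys >= 0L)
  reason <- rep(NA_character_, nrow(records))
  dup <- duplicated(records$residues)
  reason[dup] <- "redundant"
  bad_chars <- sprintf("[%s]", paste0(gsub("\\*", "\\\\*", AA_AMBIGUOUS),
                                      collapse = ""))
  incomplete <- is.na(reason) &
    (grepl(bad_chars, records$residues) |
       grepl(sprintf("[^%s]", paste0(AA_STANDARD, collapse = "")),
             records$residues))
  reason[incomplete] <- "incomplete"
  ncys <- vapply(records$residues,
                 function(s) sum(strsplit(s, "")[[1]] == "C"), integer(1),
                 USE.NAMES = FALSE)
  low_c <- is.na(reason) & ncys < min_cys
  reason[low_c] <- "cysteine_pattern"
  keep <- is.na(reason)
  structure(list(
    kept = records[keep, , drop = FALSE],
    rejected = data.frame(id = records$id[!keep], reason = reason[!keep],
                          stringsAsFactors = FALSE)
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> kept", nrow(x$kept), "/",
      nrow(x$kept) + nrow(x$rejected), "records\n")
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

#' Trim precursors to the mature inhibitor region
#'
#' The mature region is taken to start three residues before the first
#' cysteine of the best scaffold-motif match and to run to the C-terminus.
#' When the motif does not match, the first cysteine of the sequence anchors
#' the cut instead; when fewer than three residues precede the anchor the
#' start is clamped to 1. Idempotent: trimming a trimmed record changes
#' nothing.
#'
#' @param records peptide record data frame (one or more rows).
#' @param motif scaffold \code{spacing_motif} used to locate the anchor
#'   cysteine.
#' @return the records with \code{residues} cut, \code{trimmed = TRUE} and
#'   \code{trim_start} set (1-based index into the pre-trim sequence).
#' @export
trim_to_mature <- function(records, motif = cpi_motif()) {
  records <- as_peptide_records(records)
  for (i in seq_len(nrow(records))) {
    seq <- records$residues[i]
    hits <- scan_motif(seq, motif)
    c1 <- if (length(hits)) hits[1] else {
      pos <- regexpr("C", seq, fixed = TRUE)
      if (pos < 0) stop("untrimmable: no cysteine in record ", records$id[i])
      as.integer(pos)
    }
    start <- max(1L, c1 - 3L)
    records$residues[i] <- substr(seq, start, nchar(seq))
    records$trim_start[i] <- if (isTRUE(records$trimmed[i])) {
      # already mature: keep the original provenance index
      records$trim_start[i]
    } else start
    records$trimmed[i] <- TRUE
  }
  records
}

#' Write a curation rejection report as TSV
#' @param report a \code{curation_report}.
#' @param path output path; columns \code{id}, \code{reason}.
#' @export
write_rejection_report <- function(report, path) {
  utils::write.table(report$rejected, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
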