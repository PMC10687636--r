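#' Read peptide records from a FASTA file
#'
#' Headers of the form \code{id|species|source_db} are split into the three
#' fields; any other header is taken whole as the id. Sequences are
#' uppercased. Characters outside the standard alphabet are retained here
#' and dealt with by [curate()].
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a peptide record data frame with columns \code{id},
#'   \code{species}, \code{source_db}, \code{residues}, \code{trimmed},
#'   \code{trim_start}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- sub("\\s.*$", "", names(set))
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[`, character(1), 1L)
  species <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                    character(1))
  source_db <- vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_,
                      character(1))
  if (anyDuplicated(id)) {
    stop("duplicate FASTA id: ", id[duplicated(id)][1])
  }
  peptide_records(id = id, residues = toupper(as.character(set)),
                  species = species, source_db = source_db)
}

#' Construct a peptide record data frame
#'
#' @param id accession-like identifiers (unique).
#' @param residues uppercase residue strings.
#' @param species,source_db optional provenance columns.
#' @param trimmed,trim_start mature-trim state; see [trim_to_mature()].
#' @return data frame with one row per peptide.
#' @export
peptide_records <- function(id, residues, species = NA_character_,
                            source_db = NA_character_, trimmed = FALSE,
                            trim_start = NA_integer_) {
  df <- data.frame(id = as.character(id),
                   species = as.character(species),
                   source_db = as.character(source_db),
                   residues = toupper(as.character(residues)),
                   trimmed = as.logical(trimmed),
                   trim_start = as.integer(trim_start),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$residues))) stop("empty residue string")
  if (anyDuplicated(df$id)) stop("duplicate id: ", df$id[duplicated(df$id)][1])
  df
}

as_peptide_records <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    return(x)
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    return(peptide_records(ids, x))
  }
  stop("cannot interpret input as peptide records")
}

#' Write peptide records to FASTA (60-column wrap)
#'
#' Headers are re-assembled as \code{id|species|source_db} when the
#' provenance fields are present, plain \code{id} otherwise.
#'
#' @param records peptide record data frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  records <- as_peptide_records(records)
  hdr <- records$id
  has_prov <- !is.na(records$species) & !is.na(records$source_db)
  hdr[has_prov] <- paste(records$id[has_prov], records$species[has_prov],
                         records$source_db[has_prov], sep = "|")
  set <- Biostrings::BStringSet(setNames(records$residues, hdr))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
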