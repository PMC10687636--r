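#' Alignment container
#'
#' A thin container for a protein multiple alignment: ids plus equal-length
#' aligned strings over the standard residues and '-'.
#'
#' @param ids character vector of sequence ids.
#' @param seqs aligned residue strings (uppercase, may contain '-').
#' @return object of class \code{peptide_alignment} with \code{ids},
#'   \code{seqs} and \code{ncol}.
#' @export
peptide_alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (length(seqs) == 0L) stop("empty alignment")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("aligned strings have unequal lengths")
  structure(list(ids = ids, seqs = seqs, ncol = w),
            class = "peptide_alignment")
}

#' Read an aligned FASTA file into a peptide_alignment
#' @param path aligned FASTA path.
#' @export
read_alignment <- function(path) {
  rec <- read_fasta(path)
  peptide_alignment(rec$id, rec$residues)
}

#' @export
print.peptide_alignment <- function(x, ...) {
  cat("<peptide_alignment>", length(x$ids), "sequences x", x$ncol,
      "columns\n")
  invisible(x)
}

#' @export
as.matrix.peptide_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, ""))
  rownames(m) <- x$ids
  m
}

#' Per-column residue and gap frequencies of an alignment
#'
#' The denominator of every column is the number of rows, so gaps carry
#' weight: each column of the result sums to 1 over the 20 residues plus
#' the gap symbol.
#'
#' @param aln a \code{peptide_alignment}.
#' @return numeric matrix, rows = \code{c(AA_STANDARD, "-")}, columns =
#'   alignment columns.
#' @export
column_frequencies <- function(aln) {
  stopifnot(inherits(aln, "peptide_alignment"))
  m <- as.matrix(aln)
  lev <- c(AA_STANDARD, "-")
  bad <- setdiff(unique(as.vector(m)), lev)
  if (length(bad)) stop("unknown residue in alignment: ",
                        paste(bad, collapse = ","))
  apply(m, 2L, function(col) table(factor(col, levels = lev)) / length(col))
}

#' Threshold consensus row of an alignment
#'
#' Per column: the residue letter is emitted if a single residue's relative
#' frequency (gaps in the denominator) reaches the threshold; otherwise the
#' symbol of the first class in scheme order whose summed member frequency
#' reaches it (ties between classes broken toward the smaller set);
#' otherwise \code{NA}.
#'
#' @param aln a \code{peptide_alignment}.
#' @param threshold percentage in (0, 100].
#' @param scheme a [residue_class_scheme()].
#' @return character vector of length \code{aln$ncol}; \code{NA} = no call.
#' @export
consensus_at_threshold <- function(aln, threshold,
                                   scheme = residue_class_scheme()) {
  stopifnot(threshold > 0, threshold <= 100)
  freqs <- column_frequencies(aln)
  thr <- threshold / 100
  cls <- scheme$classes
  sizes <- lengths(cls)
  # stable order: scheme order, smaller set first on frequency ties
  apply(freqs, 2L, function(f) {
    res <- f[AA_STANDARD]
    top <- which(res >= thr - 1e-12)
    if (length(top)) return(names(res)[top[which.max(res[top])]])
    csum <- vapply(cls, function(members) sum(res[members]), numeric(1))
    ok <- which(csum >= thr - 1e-12)
    if (!length(ok)) return(NA_character_)
    best <- ok[1]  # scheme order decides among qualifiers ...
    for (cand in ok[-1]) {  # ... equal-frequency ties go to the smaller set
      if (abs(csum[cand] - csum[best]) < 1e-12 && sizes[cand] < sizes[best]) {
        best <- cand
      }
    }
    names(cls)[best]
  })
}

#' Consensus profile at several thresholds plus the frequency matrix
#'
#' @param aln a \code{peptide_alignment}.
#' @param thresholds percentages, default \code{c(100, 90, 80, 70)}.
#' @param scheme a [residue_class_scheme()].
#' @return object of class \code{consensus_profile}: list with
#'   \code{thresholds}, \code{calls} (matrix thresholds x columns) and
#'   \code{freqs} (see [column_frequencies()]).
#' @export
consensus_profile <- function(aln, thresholds = c(100, 90, 80, 70),
                              scheme = residue_class_scheme()) {
  calls <- t(vapply(thresholds,
                    function(t) consensus_at_threshold(aln, t, scheme),
                    character(aln$ncol)))
  rownames(calls) <- paste0(thresholds, "%")
  structure(list(thresholds = thresholds, calls = calls,
                 freqs = column_frequencies(aln)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile>", ncol(x$calls), "columns at thresholds",
      paste(x$thresholds, collapse = "/"), "%\n")
  for (i in seq_len(nrow(x$calls))) {
    row <- x$calls[i, ]
    row[is.na(row)] <- "."
    cat(sprintf("%5s ", rownames(x$calls)[i]), paste(row, collapse = ""),
        "\n", sep = "")
  }
  invisible(x)
}

#' Derive the cysteine/aspartate spacing motif from an alignment
#'
#' Anchor columns are the first five alignment columns whose cysteine
#' frequency reaches \code{anchor_threshold}, plus the aspartate column
#' immediately preceding the third such cysteine column when its D
#' frequency also reaches the threshold. The spacer between consecutive
#' anchors is the modal count, over rows carrying both anchors, of
#' residues strictly between them in the degapped row (ties broken toward
#' the smaller spacer).
#'
#' @param aln a \code{peptide_alignment}.
#' @param anchor_threshold percentage, default 90.
#' @return a \code{spacing_motif}.
#' @export
derive_spacing_motif <- function(aln, anchor_threshold = 90) {
  freqs <- column_frequencies(aln)
  thr <- anchor_threshold / 100 - 1e-12
  c_cols <- which(freqs["C", ] >= thr)
  if (length(c_cols) < 5L) stop("scaffold not found: fewer than five ",
                                "conserved cysteine columns")
  c_cols <- c_cols[1:5]
  anchor_cols <- c_cols
  anchor_res <- rep("C", 5L)
  d_col <- c_cols[3] - 1L
  if (d_col >= 1L && !(d_col %in% c_cols) && freqs["D", d_col] >= thr) {
    anchor_cols <- sort(c(anchor_cols, d_col))
    anchor_res <- ifelse(anchor_cols == d_col, "D", "C")
  }
  m <- as.matrix(aln)
  spacers <- integer(length(anchor_cols) - 1L)
  for (k in seq_along(spacers)) {
    a <- anchor_cols[k]; b <- anchor_cols[k + 1L]
    rows_ok <- m[, a] == anchor_res[k] & m[, b] == anchor_res[k + 1L]
    if (!any(rows_ok)) stop("scaffold not found: no row carries anchors ",
                            k, " and ", k + 1L)
    between <- if (b - a > 1L) {
      apply(m[rows_ok, (a + 1L):(b - 1L), drop = FALSE], 1L,
            function(r) sum(r != "-"))
    } else rep(0L, sum(rows_ok))
    tab <- table(between)
    modal <- as.integer(names(tab)[tab == max(tab)])
    spacers[k] <- min(modal)
  }
  spacing_motif(anchor_res, spacers)
}

#' Write consensus calls and frequency matrix as TSV
#'
#' @param profile a \code{consensus_profile}.
#' @param calls_path,freqs_path output paths; either may be \code{NULL}.
#' @export
write_consensus_tsv <- function(profile, calls_path = NULL,
                                freqs_path = NULL) {
  if (!is.null(calls_path)) {
    df <- data.frame(column = seq_len(ncol(profile$calls)),
                     t(profile$calls), check.names = FALSE)
    names(df)[-1] <- paste0("call_", profile$thresholds)
    utils::write.table(df, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  if (!is.null(freqs_path)) {
    df <- data.frame(residue = rownames(profile$freqs), profile$freqs,
                     check.names = FALSE)
    names(df)[-1] <- paste0("col", seq_len(ncol(profile$freqs)))
    utils::write.table(df, freqs_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
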