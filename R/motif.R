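#' Spacing motifs: fixed anchor residues separated by fixed-length wildcards
#'
#' A spacing motif is an ordered list of anchor residues (one-letter codes)
#' with a fixed number of wildcard positions ("X", any standard residue)
#' between consecutive anchors. The family's scaffold motif,
#' \code{CXXXCXXXXDCXXXXXCXXC}, carries five cysteines and one aspartate in
#' this form.
#'
#' @param anchors character vector of single residue letters (uppercase).
#' @param spacers integer vector of wildcard counts between consecutive
#'   anchors; length must be \code{length(anchors) - 1}.
#' @return An object of class \code{spacing_motif} with elements
#'   \code{anchors} and \code{spacers}.
#' @examples
#' m <- spacing_motif(c("C", "C", "D", "C", "C", "C"), c(3, 4, 0, 5, 2))
#' format(m)                    # "CXXXCXXXXDCXXXXXCXXC"
#' format(m, style = "prosite") # "C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C"
#' @export
spacing_motif <- function(anchors, spacers = integer(0)) {
  anchors <- toupper(as.character(anchors))
  spacers <- as.integer(spacers)
  if (length(anchors) < 1L) stop("motif needs at least one anchor")
  if (!all(anchors %in% AA_STANDARD)) {
    stop("anchors must be standard one-letter residue codes")
  }
  if (length(spacers) != length(anchors) - 1L) {
    stop("need exactly length(anchors) - 1 spacer lengths")
  }
  if (any(spacers < 0L)) stop("spacer lengths must be >= 0")
  structure(list(anchors = anchors, spacers = spacers),
            class = "spacing_motif")
}

#' Default inhibitor scaffold motif C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C
#'
#' @return the 20-position, 6-anchor \code{spacing_motif} (5 Cys + 1 Asp).
#' @export
cpi_motif <- function() {
  spacing_motif(c("C", "C", "D", "C", "C", "C"), c(3L, 4L, 0L, 5L, 2L))
}

#' Parse a motif from compact or PROSITE-like text
#'
#' Accepts both \code{"CXXXCXXXXDCXXXXXCXXC"} and
#' \code{"C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C"}; parsing then formatting
#' round-trips.
#'
#' @param text motif text in either syntax.
#' @return a \code{spacing_motif}.
#' @export
parse_motif <- function(text) {
  text <- trimws(text)
  if (grepl("-", text, fixed = TRUE) || grepl("x(", text, fixed = TRUE)) {
    parts <- strsplit(text, "-", fixed = TRUE)[[1]]
    expanded <- character(0)
    for (p in parts) {
      m <- regmatches(p, regexec("^[xX]\\((\\d+)\\)$", p))[[1]]
      if (length(m) == 2L) {
        expanded <- c(expanded, rep("X", as.integer(m[2])))
      } else if (grepl("^[xX]$", p)) {
        expanded <- c(expanded, "X")
      } else if (nchar(p) == 1L) {
        expanded <- c(expanded, toupper(p))
      } else {
        stop("cannot parse motif element: ", p)
      }
    }
    text <- paste(expanded, collapse = "")
  }
  chars <- strsplit(toupper(text), "")[[1]]
  if (!length(chars)) stop("empty motif text")
  anchor_idx <- which(chars != "X")
  if (!length(anchor_idx)) stop("motif has no anchors")
  if (anchor_idx[1] != 1L || anchor_idx[length(anchor_idx)] != length(chars)) {
    stop("motif must start and end with an anchor residue")
  }
  spacing_motif(chars[anchor_idx], diff(anchor_idx) - 1L)
}

#' @export
format.spacing_motif <- function(x, style = c("compact", "prosite"), ...) {
  style <- match.arg(style)
  if (style == "compact") {
    out <- x$anchors[1]
    for (i in seq_along(x$spacers)) {
      out <- paste0(out, strrep("X", x$spacers[i]), x$anchors[i + 1])
    }
    out
  } else {
    parts <- x$anchors[1]
    for (i in seq_along(x$spacers)) {
      if (x$spacers[i] > 0) parts <- c(parts, sprintf("x(%d)", x$spacers[i]))
      parts <- c(parts, x$anchors[i + 1])
    }
    paste(parts, collapse = "-")
  }
}

#' @export
print.spacing_motif <- function(x, ...) {
  cat("<spacing_motif> ", format(x), "  [",
      format(x, style = "prosite"), "]\n", sep = "")
  invisible(x)
}

#' Total length (in residues) of a motif instance
#' @param motif a \code{spacing_motif}.
#' @export
motif_length <- function(motif) {
  length(motif$anchors) + sum(motif$spacers)
}

#' Scan a sequence for motif matches
#'
#' Reports every 1-based start position where the anchors occur with exactly
#' the configured spacers; wildcard positions match any standard residue.
#' Overlapping matches are all reported; matching is anywhere in the
#' sequence, not anchored.
#'
#' @param seq ungapped residue text (uppercase one-letter codes).
#' @param motif a \code{spacing_motif} (default \code{cpi_motif()}).
#' @return integer vector of match start positions (possibly empty).
#' @examples
#' scan_motif("CAAACAAAADCAAAAACAAC")            # 1
#' scan_motif("CAAACAAAAECAAAAACAAC")            # integer(0): D anchor broken
#' @export
scan_motif <- function(seq, motif = cpi_motif()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("-", seq, fixed = TRUE)) stop("sequence must be ungapped")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  mlen <- motif_length(motif)
  if (L < mlen) return(integer(0))
  offsets <- cumsum(c(0L, motif$spacers + 1L))  # anchor offsets from start
  starts <- seq_len(L - mlen + 1L)
  ok <- rep(TRUE, length(starts))
  for (i in seq_along(motif$anchors)) {
    ok <- ok & chars[starts + offsets[i]] == motif$anchors[i]
  }
  # wildcards must still be standard residues
  if (any(!chars %in% AA_STANDARD)) {
    std <- chars %in% AA_STANDARD
    cum <- cumsum(std)
    nstd <- cum[starts + mlen - 1L] - c(0L, cum)[starts]
    ok <- ok & nstd == mlen
  }
  starts[ok]
}

#' Fraction of records matched by a motif, as a percentage
#'
#' @param records a peptide record data frame (see [read_fasta()]).
#' @param motif a \code{spacing_motif}.
#' @return percentage in \code{[0, 100]} of records with at least one match.
#' @export
motif_match_rate <- function(records, motif = cpi_motif()) {
  records <- as_peptide_records(records)
  if (nrow(records) == 0L) stop("no records given")
  hit <- vapply(records$residues,
                function(s) length(scan_motif(s, motif)) > 0L, logical(1),
                USE.NAMES = FALSE)
  100 * sum(hit) / nrow(records)
}
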