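#' Configuration for the synthetic inhibitor-family generator
#'
#' Describes the statistical world the pipeline assumes: a family of
#' ~35-50-residue cysteine-rich peptides built on the
#' \code{C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C} scaffold, with class-biased
#' inter-cysteine segments (turnlike between the first two cysteines;
#' polar/small/turnlike before the aspartate; hydrophobic after the third
#' cysteine; no preference in the last spacer), a hydrophobic-biased
#' C-terminal tail, an optional N-terminal propeptide, and a controllable
#' fraction of motif-violating decoys.
#'
#' @param n_sequences family size (default 42, the curated family size the
#'   generator emulates).
#' @param seed integer seed; everything downstream is reproducible from it.
#' @param scaffold a \code{spacing_motif}.
#' @param segment_classes list, one element per scaffold spacer segment:
#'   a character vector of class symbols the segment prefers, or
#'   \code{NULL} for no preference (uniform over the 20 residues).
#' @param tail_range inclusive range of the hydrophobic C-terminal tail
#'   length; one length is drawn per family so that the mature regions
#'   stack gaplessly into an alignment.
#' @param propeptide_range inclusive range of the N-terminal propeptide
#'   length (default 0-25), drawn per sequence.
#' @param violation_rate fraction of sequences given exactly one
#'   anchor-destroying substitution; the count is \code{round(n * rate)}.
#' @param substitution_noise per-wildcard-position probability of drawing
#'   uniformly over the 20 residues instead of from the preferred class.
#' @param scheme the [residue_class_scheme()] the class symbols refer to.
#' @export
synthetic_config <- function(n_sequences = 42L, seed = 1L,
                             scaffold = cpi_motif(),
                             segment_classes = list("t", c("p", "s", "t"),
                                                    NULL, "h", NULL),
                             tail_range = c(2L, 6L),
                             propeptide_range = c(0L, 25L),
                             violation_rate = 0,
                             substitution_noise = 0.1,
                             scheme = residue_class_scheme()) {
  stopifnot(n_sequences >= 1L, violation_rate >= 0, violation_rate <= 1,
            substitution_noise >= 0, substitution_noise <= 1,
            length(segment_classes) == length(scaffold$spacers))
  for (seg in segment_classes) {
    if (!is.null(seg)) {
      bad <- setdiff(seg, names(scheme$classes))
      if (length(bad)) stop("unknown class symbol(s): ",
                            paste(bad, collapse = ","))
      if (!length(unique(unlist(scheme$classes[seg])))) {
        stop("empty class set for segment preference")
      }
    }
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 seed = as.integer(seed), scaffold = scaffold,
                 segment_classes = segment_classes,
                 tail_range = as.integer(tail_range),
                 propeptide_range = as.integer(propeptide_range),
                 violation_rate = violation_rate,
                 substitution_noise = substitution_noise,
                 scheme = scheme),
            class = "synthetic_config")
}

draw_biased <- function(n, pool, noise) {
  from_pool <- stats::runif(n) >= noise
  out <- character(n)
  out[from_pool] <- sample(pool, sum(from_pool), replace = TRUE)
  out[!from_pool] <- sample(AA_STANDARD, sum(!from_pool), replace = TRUE)
  out
}

#' Generate a synthetic inhibitor family
#'
#' Draws \code{cfg$n_sequences} peptides: an optional uniform propeptide,
#' three uniform lead residues, the scaffold with class-biased wildcard
#' segments, and a hydrophobic tail. Exactly \code{round(n *
#' violation_rate)} sequences receive one anchor-destroying substitution
#' (re-drawn if the damaged sequence still matches the scaffold anywhere,
#' so truth labels always agree with the scanner). The mature regions
#' (propeptide excluded) all share one length and are stacked gaplessly as
#' the alignment.
#'
#' @param cfg a [synthetic_config()].
#' @return list with \code{records} (full sequences, untrimmed),
#'   \code{aln} (gapless \code{peptide_alignment} of mature regions) and
#'   \code{truth} (data frame \code{id}, \code{violates}).
#' @export
generate_family <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_sequences
  scaffold <- cfg$scaffold
  hydro <- cfg$scheme$classes[["h"]]
  tail_len <- sample(seq(cfg$tail_range[1], cfg$tail_range[2]), 1L)
  lead_pool <- setdiff(AA_STANDARD, "C")  # keep the anchor Cys the first

  mature <- character(n)
  for (s in seq_len(n)) {
    parts <- character(0)
    for (k in seq_along(scaffold$anchors)) {
      parts <- c(parts, scaffold$anchors[k])
      if (k <= length(scaffold$spacers) && scaffold$spacers[k] > 0) {
        pref <- cfg$segment_classes[[k]]
        pool <- if (is.null(pref)) AA_STANDARD else
          unique(unlist(cfg$scheme$classes[pref]))
        parts <- c(parts, draw_biased(scaffold$spacers[k], pool,
                                      cfg$substitution_noise))
      }
    }
    lead <- sample(lead_pool, 3L, replace = TRUE)
    tail <- draw_biased(tail_len, hydro, cfg$substitution_noise)
    mature[s] <- paste(c(lead, parts, tail), collapse = "")
  }

  n_viol <- round(n * cfg$violation_rate)
  viol_idx <- if (n_viol > 0) sort(sample.int(n, n_viol)) else integer(0)
  anchor_offsets <- cumsum(c(0L, scaffold$spacers + 1L))
  for (s in viol_idx) {
    repeat {
      k <- sample.int(length(scaffold$anchors), 1L)
      pos <- 3L + 1L + anchor_offsets[k]   # anchor position within mature
      repl <- sample(setdiff(AA_STANDARD, scaffold$anchors[k]), 1L)
      cand <- mature[s]
      substr(cand, pos, pos) <- repl
      if (!length(scan_motif(cand, scaffold))) { mature[s] <- cand; break }
    }
  }

  prop_len <- sample(seq(cfg$propeptide_range[1], cfg$propeptide_range[2]),
                     n, replace = TRUE)
  full <- vapply(seq_len(n), function(s) {
    pre <- if (prop_len[s] > 0) {
      paste(sample(AA_STANDARD, prop_len[s], replace = TRUE), collapse = "")
    } else ""
    paste0(pre, mature[s])
  }, character(1))

  ids <- sprintf("SYN%03d", seq_len(n))
  list(records = peptide_records(ids, full, species = "synthetic",
                                 source_db = "generator"),
       aln = peptide_alignment(ids, mature),
       truth = data.frame(id = ids,
                          violates = seq_len(n) %in% viol_idx,
                          stringsAsFactors = FALSE))
}

#' Generate scaffold-free decoy peptides
#'
#' Uniform-random sequences, rejection-sampled so that none matches the
#' scaffold motif anywhere; negatives for scanner specificity tests.
#'
#' @param n number of decoys.
#' @param length_range inclusive length range (default 35-50).
#' @param seed integer seed.
#' @param scaffold the motif the decoys must not contain.
#' @return a peptide record data frame.
#' @export
generate_decoys <- function(n, length_range = c(35L, 50L), seed = 1L,
                            scaffold = cpi_motif()) {
  stopifnot(n >= 1L)
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    repeat {
      s <- paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
      if (!length(scan_motif(s, scaffold))) return(s)
    }
  }, character(1))
  peptide_records(sprintf("DECOY%03d", seq_len(n)), seqs,
                  species = "synthetic", source_db = "generator")
}
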