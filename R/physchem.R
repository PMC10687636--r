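#' Physicochemical constants for the peptide panel
#'
#' Bundles the numeric conventions behind the panel: average residue masses
#' (IUPAC, as used by Expasy-style MW calculators), the water mass added
#' once per chain, the Bjellqvist pKa set used for pI (with per-residue
#' N-terminal overrides), the hydrophobic residue set used for the
#' hydrophobicity ratio, and the Boman (2003) per-residue protein-binding
#' scale in kcal/mol (sign convention: higher = stronger binding
#' potential).
#'
#' @param masses named numeric, average residue mass in Da per one-letter
#'   code.
#' @param water mass of water in Da.
#' @param pka named numeric with entries \code{Cterm}, \code{Nterm},
#'   \code{D}, \code{E}, \code{C}, \code{Y}, \code{H}, \code{K}, \code{R}.
#' @param nterm_overrides named numeric of N-terminal pKa values keyed by
#'   first residue, overriding \code{pka["Nterm"]}.
#' @param hydrophobic residue set for the hydrophobicity ratio.
#' @param boman named numeric Boman scale over all 20 residues.
#' @return object of class \code{physchem_constants}.
#' @export
physchem_constants <- function(
    masses = c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
               C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
               H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
               M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
               T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326),
    water = 18.01524,
    pka = c(Cterm = 3.55, Nterm = 7.5, D = 4.05, E = 4.45, C = 9.0,
            Y = 10.0, H = 5.98, K = 10.0, R = 12.0),
    nterm_overrides = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                        V = 7.44, E = 7.70),
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W"),
    boman = c(A = -1.81, R = 14.92, N = 6.64, D = 8.72, C = -1.28,
              Q = 5.54, E = 6.81, G = -0.94, H = 4.66, I = -4.92,
              L = -4.92, K = 5.55, M = -2.35, F = -2.98, P = 0.00,
              S = 3.40, T = 2.57, W = -2.33, Y = 0.14, V = -4.04)) {
  for (tab in list(masses, boman)) {
    if (!all(AA_STANDARD %in% names(tab))) {
      stop("masses and boman scale must cover all 20 standard residues")
    }
  }
  structure(list(masses = masses, water = water, pka = pka,
                 nterm_overrides = nterm_overrides,
                 hydrophobic = hydrophobic, boman = boman),
            class = "physchem_constants")
}

split_residues <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  bad <- setdiff(chars, AA_STANDARD)
  if (length(bad)) stop("unknown residue: ", paste(unique(bad), collapse = ","))
  chars
}

#' Average molecular weight of a peptide, in Da
#'
#' Sum of average residue masses plus one water mass, reported to two
#' decimals. Additive: \code{MW(ab) == MW(a) + MW(b) - water}.
#'
#' @param seq ungapped residue text.
#' @param constants a [physchem_constants()].
#' @export
molecular_weight <- function(seq, constants = physchem_constants()) {
  chars <- split_residues(seq)
  round(sum(constants$masses[chars]) + constants$water, 2)
}

#' Continuous Henderson-Hasselbalch net charge at a given pH
#'
#' Positive terms: N-terminus, His, Lys, Arg; negative terms: C-terminus,
#' Asp, Glu, Cys, Tyr. Strictly decreasing in pH.
#'
#' @param seq ungapped residue text.
#' @param ph pH value.
#' @param constants a [physchem_constants()].
#' @return net charge in elementary-charge units (not rounded).
#' @export
net_charge_continuous <- function(seq, ph, constants = physchem_constants()) {
  chars <- split_residues(seq)
  pka <- constants$pka
  nterm_pka <- constants$nterm_overrides[chars[1]]
  if (is.na(nterm_pka)) nterm_pka <- pka[["Nterm"]]
  pos_pkas <- c(nterm_pka, rep(pka[["H"]], sum(chars == "H")),
                rep(pka[["K"]], sum(chars == "K")),
                rep(pka[["R"]], sum(chars == "R")))
  neg_pkas <- c(pka[["Cterm"]], rep(pka[["D"]], sum(chars == "D")),
                rep(pka[["E"]], sum(chars == "E")),
                rep(pka[["C"]], sum(chars == "C")),
                rep(pka[["Y"]], sum(chars == "Y")))
  sum(1 / (1 + 10^(ph - pos_pkas))) - sum(1 / (1 + 10^(neg_pkas - ph)))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] at which [net_charge_continuous()] vanishes.
#' The charge function is strictly decreasing in pH so the root is unique.
#' Returned at bisection precision; [physchem_table()] reports it to 2
#' decimals.
#'
#' @param seq ungapped residue text.
#' @param constants a [physchem_constants()].
#' @param tol bisection tolerance in pH units (default 0.001).
#' @export
isoelectric_point <- function(seq, constants = physchem_constants(),
                              tol = 0.001) {
  stopifnot(tol > 0)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge_continuous(seq, mid, constants) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Formal net charge (pH-7 integer convention)
#'
#' Counts \code{(K + R) - (D + E)}; histidine and the termini are excluded,
#' which reproduces the small-integer charges conventionally reported for
#' peptides of this family.
#'
#' @param seq ungapped residue text.
#' @export
net_charge <- function(seq) {
  chars <- split_residues(seq)
  sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E"))
}

#' Hydrophobic residue ratio, in percent
#'
#' 100 x (residues in the hydrophobic set) / length, rounded to the nearest
#' integer.
#'
#' @param seq ungapped residue text.
#' @param constants a [physchem_constants()].
#' @export
hydrophobic_ratio <- function(seq, constants = physchem_constants()) {
  chars <- split_residues(seq)
  if (!length(chars)) stop("empty sequence")
  round(100 * sum(chars %in% constants$hydrophobic) / length(chars))
}

#' Boman protein-binding index, in kcal/mol
#'
#' Arithmetic mean of the per-residue Boman scale values; higher values
#' indicate stronger protein-binding (hence antimicrobial-interaction)
#' potential. Linear: the index of a concatenation is the length-weighted
#' mean of the parts.
#'
#' @param seq ungapped residue text.
#' @param constants a [physchem_constants()].
#' @export
boman_index <- function(seq, constants = physchem_constants()) {
  chars <- split_residues(seq)
  round(mean(constants$boman[chars]), 2)
}

#' Physicochemical panel for a set of peptide records
#'
#' One row per record, in input order: molecular weight, pI, formal
#' charge, hydrophobic ratio and Boman index.
#'
#' @param records peptide record data frame (normally mature/trimmed).
#' @param constants a [physchem_constants()].
#' @return data frame with columns \code{id}, \code{species}, \code{pI},
#'   \code{MW_Da}, \code{charge}, \code{hydrophobic_pct},
#'   \code{boman_kcal_mol}.
#' @export
physchem_table <- function(records, constants = physchem_constants()) {
  records <- as_peptide_records(records)
  if (nrow(records) == 0L) {
    return(data.frame(id = character(0), species = character(0),
                      pI = numeric(0), MW_Da = numeric(0),
                      charge = integer(0), hydrophobic_pct = numeric(0),
                      boman_kcal_mol = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    seq <- records$residues[i]
    tryCatch(
      data.frame(id = records$id[i],
                 species = if ("species" %in% names(records))
                   records$species[i] else NA_character_,
                 pI = round(isoelectric_point(seq, constants), 2),
                 MW_Da = molecular_weight(seq, constants),
                 charge = net_charge(seq),
                 hydrophobic_pct = hydrophobic_ratio(seq, constants),
                 boman_kcal_mol = boman_index(seq, constants),
                 stringsAsFactors = FALSE),
      error = function(e) stop("record ", records$id[i], ": ",
                               conditionMessage(e), call. = FALSE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
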