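#' @importFrom stats setNames
NULL

#' The 20 standard one-letter amino-acid codes
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ambiguity / non-standard codes that mark a sequence as incomplete
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*")

#' Residue class scheme for threshold consensus calls
#'
#' Five Taylor-style physicochemical classes matching the consensus symbols
#' used for this family: h (hydrophobic), o (alcohol), p (polar), s (small),
#' t (turnlike). The exact memberships are a convention, not a measurement,
#' so they are configurable; defaults below are the ones the package's
#' consensus calls are calibrated to.
#'
#' @param classes named list mapping single class symbols to character
#'   vectors of member residues. Order matters: at a given threshold the
#'   first qualifying class in this order wins (ties broken toward the
#'   smaller set).
#' @return object of class \code{residue_class_scheme}.
#' @export
residue_class_scheme <- function(classes = list(
    h = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
    o = c("S", "T"),
    p = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T"),
    s = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
    t = c("A", "C", "D", "E", "G", "H", "K", "N", "Q", "R", "S", "T"))) {
  if (is.null(names(classes)) || any(names(classes) == "") ||
      anyDuplicated(names(classes))) {
    stop("classes must be uniquely named by single symbols")
  }
  for (nm in names(classes)) {
    bad <- setdiff(classes[[nm]], AA_STANDARD)
    if (length(bad)) {
      stop("class '", nm, "' contains non-standard residues: ",
           paste(bad, collapse = ","))
    }
  }
  structure(list(classes = lapply(classes, unique)),
            class = "residue_class_scheme")
}
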