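# Shared fixtures: all generated in code, nothing read from disk.

random_peptides <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
  }, character(1))
}

# independent regular-expression oracle for the motif scanner:
# overlapping matches via a zero-width lookahead
regex_scan_oracle <- function(seq, motif = cpi_motif()) {
  aa <- paste0("[", paste(AA_STANDARD, collapse = ""), "]")
  pat <- motif$anchors[1]
  for (i in seq_along(motif$spacers)) {
    pat <- paste0(pat, strrep(aa, motif$spacers[i]), motif$anchors[i + 1])
  }
  hits <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# independent fine-grid oracle for the isoelectric point: evaluates the
# Henderson-Hasselbalch charge on a dense pH grid (vectorized) and returns
# the grid point of minimal |charge|
grid_pi_oracle <- function(seq, constants = physchem_constants(),
                           step = 1e-4) {
  grid <- seq(0, 14, by = step)
  ch <- strsplit(seq, "")[[1]]
  pka <- constants$pka
  nt <- constants$nterm_overrides[ch[1]]
  if (is.na(nt)) nt <- pka[["Nterm"]]
  pos <- c(nt, rep(pka[["H"]], sum(ch == "H")),
           rep(pka[["K"]], sum(ch == "K")), rep(pka[["R"]], sum(ch == "R")))
  neg <- c(pka[["Cterm"]], rep(pka[["D"]], sum(ch == "D")),
           rep(pka[["E"]], sum(ch == "E")), rep(pka[["C"]], sum(ch == "C")),
           rep(pka[["Y"]], sum(ch == "Y")))
  charge <- rowSums(1 / (1 + 10^outer(grid, pos, `-`))) -
    rowSums(1 / (1 + 10^outer(-grid, -neg, `-`)))
  grid[which.min(abs(charge))]
}

# write a structure_model out as fixed-column PDB text
write_pdb_text <- function(model, path, extra_lines = character(0)) {
  lines <- vapply(seq_len(nrow(model)), function(i) {
    atom <- model$atom[i]
    # short atom names start in column 14 by PDB convention
    name_field <- if (nchar(atom) < 4L) sprintf(" %-3s", atom) else atom
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, name_field, model$resname[i], model$chain[i], model$resno[i],
            model$x[i], model$y[i], model$z[i], 1.0, 0.0, model$element[i])
  }, character(1))
  writeLines(c(lines, extra_lines, "END"), path)
  path
}

# idealized aromatic 6-ring (radius 1.39 A) centered at `center`, lying in
# the plane spanned by unit vectors u and v
hex_ring_coords <- function(center, u, v, radius = 1.39) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(ang, function(a) {
    center + radius * (cos(a) * u + sin(a) * v)
  }, numeric(3)))
}

phe_ring_model <- function(chain, resno, center, u, v) {
  xyz <- hex_ring_coords(center, u, v)
  structure_model(chain = rep(chain, 6), resname = rep("PHE", 6),
                  resno = rep(resno, 6),
                  atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

rbind_models <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  class(df) <- c("structure_model", "data.frame")
  df
}

# single-interaction toy models, one per detector type
fixture_hbond <- function() {
  structure_model(chain = c("A", "A", "B", "B"),
                  resname = c("GLY", "GLY", "GLY", "GLY"),
                  resno = c(1, 1, 2, 2),
                  atom = c("N", "CA", "C", "O"),
                  x = c(0, -1.0, 3.9, 2.9), y = c(0, 0.8, 0.5, 0),
                  z = c(0, 0, 0, 0))
}

fixture_charge <- function() {
  structure_model(chain = c("A", "B"), resname = c("ARG", "ASP"),
                  resno = c(10, 5), atom = c("NH1", "OD1"),
                  x = c(0, 4.0), y = c(0, 0), z = c(0, 0))
}

fixture_pipi <- function() {
  # perpendicular rings, centroids 5.0 A apart -> one T-shaped contact
  rbind_models(
    phe_ring_model("A", 30, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    phe_ring_model("B", 40, c(5, 0, 0), c(1, 0, 0), c(0, 0, 1)))
}

fixture_pialkyl <- function() {
  rbind_models(
    phe_ring_model("A", 50, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    structure_model(chain = "B", resname = "ALA", resno = 20, atom = "CB",
                    x = 0, y = 0, z = 4.2))
}

# rigid motion: rotate by a seeded random orthogonal matrix, then translate
rigid_transform <- function(model, seed = 1) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- rnorm(3, sd = 10)
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(R)
  model$x <- xyz[, 1] + shift[1]
  model$y <- xyz[, 2] + shift[2]
  model$z <- xyz[, 3] + shift[3]
  model
}

# additive 4-taxon tree metric: ((A:1,B:2):4,(C:2,D:3)) as a matrix
additive_4taxon_dm <- function() {
  matrix(c(0, 3, 7, 8,
           3, 0, 8, 9,
           7, 8, 0, 5,
           8, 9, 5, 0), 4, 4,
         dimnames = list(LETTERS[1:4], LETTERS[1:4]))
}

# exhaustive oracle for additive matrices on 4 or 5 taxa: a 2-subset is a
# cherry (internal edge) iff it satisfies the four-point condition against
# every quartet it appears in; returns those 2-subsets as canonical keys
exhaustive_cherry_oracle <- function(dm) {
  ids <- rownames(dm)
  stopifnot(length(ids) %in% c(4L, 5L))
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  good <- Filter(function(p) {
    rest <- setdiff(ids, p)
    quartets <- if (length(rest) >= 2L) {
      utils::combn(rest, 2, simplify = FALSE)
    } else list()
    all(vapply(quartets, function(q) {
      s1 <- dm[p[1], p[2]] + dm[q[1], q[2]]
      s2 <- dm[p[1], q[1]] + dm[p[2], q[2]]
      s3 <- dm[p[1], q[2]] + dm[p[2], q[1]]
      s1 <= min(s2, s3) + 1e-9 && abs(s2 - s3) < 1e-9
    }, logical(1)))
  }, pairs)
  sort(vapply(good, function(p) paste(sort(p), collapse = "|"),
              character(1)))
}

# 2-vs-rest split keys of an unrooted phylo tree, canonicalized to the
# 2-taxon side (comparable with exhaustive_cherry_oracle output)
tree_cherry_keys <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    other <- sort(setdiff(tree$tip.label, side))
    if (length(side) == 2L && length(other) >= 2L) {
      keys <- c(keys, paste(side, collapse = "|"))
    }
    if (length(other) == 2L && length(side) >= 2L) {
      keys <- c(keys, paste(other, collapse = "|"))
    }
  }
  sort(unique(keys))
}
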