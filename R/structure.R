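#' Parse a protein structure from PDB-format text
#'
#' Loads ATOM and HETATM records of the first model (NMR-style multi-model
#' files contribute model 1 only). Alternate locations are resolved per
#' (chain, residue, atom) by highest occupancy, then altloc 'A', then file
#' order.
#'
#' @param path path to a PDB file.
#' @return object of class \code{structure_model}: a data frame of atoms
#'   with columns \code{chain}, \code{resname}, \code{resno}, \code{atom},
#'   \code{element}, \code{x}, \code{y}, \code{z}.
#' @export
parse_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rectype <- substr(lines, 1, 6)
  end1 <- which(rectype == "ENDMDL")[1]
  if (!is.na(end1)) lines <- lines[seq_len(end1)]
  sel <- which(substr(lines, 1, 6) %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM records in ", path)
  ln <- lines[sel]
  num <- function(s, from, to, what, lineno) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    bad <- which(is.na(v))
    if (length(bad)) stop("malformed ", what, " field at line ",
                          lineno[bad[1]])
    v
  }
  atoms <- data.frame(
    atom = trimws(substr(ln, 13, 16)),
    altloc = substr(ln, 17, 17),
    resname = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    resno = as.integer(num(ln, 23, 26, "residue number", sel)),
    x = num(ln, 31, 38, "x coordinate", sel),
    y = num(ln, 39, 46, "y coordinate", sel),
    z = num(ln, 47, 54, "z coordinate", sel),
    occupancy = suppressWarnings(as.numeric(substr(ln, 55, 60))),
    element = trimws(substr(ln, 77, 78)),
    stringsAsFactors = FALSE)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  # infer element from the atom name when column 77-78 is blank
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- substr(gsub("[0-9']", "", atoms$atom[blank]), 1, 1)
  # altloc resolution: best occupancy, then altloc 'A', then file order
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  ord <- order(key, -atoms$occupancy, atoms$altloc != "A",
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom,
                                   sep = "\r")), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)), atoms$resno),
                 c("chain", "resname", "resno", "atom", "element",
                   "x", "y", "z")]
  rownames(atoms) <- NULL
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in ", path)
  }
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Build a structure model from scratch (for fixtures and tests)
#'
#' @param chain,resname,resno,atom,x,y,z parallel vectors, one entry per
#'   atom.
#' @param element optional; inferred from the atom name when omitted.
#' @export
structure_model <- function(chain, resname, resno, atom, x, y, z,
                            element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9']", "", atom), 1, 1)
  df <- data.frame(chain = chain, resname = resname,
                   resno = as.integer(resno), atom = atom,
                   element = element, x = x, y = y, z = z,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(df$chain, df$resno, df$atom))) {
    stop("(chain, residue number, atom name) must be unique")
  }
  class(df) <- c("structure_model", "data.frame")
  df
}

# resolve a "CHAIN:RESNAME###:ATOM" selector to atom row indices
resolve_selector <- function(model, sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || length(parts) > 3L) {
    stop("bad selector syntax: ", sel)
  }
  m <- regexec("^([A-Za-z]{1,3})(-?\\d+)$", parts[2])[[1]]
  res <- regmatches(parts[2], list(m))[[1]]
  if (length(res) != 3L) stop("bad residue selector in: ", sel)
  idx <- which(model$chain == parts[1] & model$resname == res[2] &
                 model$resno == as.integer(res[3]))
  if (length(parts) == 3L) idx <- idx[model$atom[idx] == parts[3]]
  if (!length(idx)) stop("selector resolves to no atom: ", sel)
  idx
}

#' Distance between two selected atoms, in Angstrom
#'
#' @param model a \code{structure_model}.
#' @param sel1,sel2 selectors of the form \code{"A:ARG127:NH1"}; each must
#'   resolve to exactly one atom.
#' @return Euclidean distance rounded to 2 decimals.
#' @export
atom_distance <- function(model, sel1, sel2) {
  i <- resolve_selector(model, sel1)
  j <- resolve_selector(model, sel2)
  if (length(i) != 1L) stop("selector not unique: ", sel1)
  if (length(j) != 1L) stop("selector not unique: ", sel2)
  round(sqrt(sum((unlist(model[i, c("x", "y", "z")]) -
                    unlist(model[j, c("x", "y", "z")]))^2)), 2)
}

#' Geometric cutoffs for interface interaction typing
#'
#' Defaults follow common interaction-profiler conventions: 3.5 A
#' donor-acceptor for hydrogen bonds (heavy-atom, since crystal structures
#' rarely carry hydrogens), 5.6 A for charge-charge contacts, 6.0 A
#' centroid-centroid with a 60-90 degree inter-plane angle for T-shaped
#' pi-pi, and 5.5 A centroid-to-carbon for pi-alkyl.
#'
#' @param hbond_max,charge_max,pipi_max,pialkyl_max distance cutoffs in A.
#' @param pipi_angle inter-plane angle window in degrees (within [0, 90]).
#' @param his_positive treat histidine as positively charged for
#'   attractive-charge detection (default \code{FALSE}; protonation is
#'   structure-dependent).
#' @export
geometry_params <- function(hbond_max = 3.5, charge_max = 5.6,
                            pipi_max = 6.0, pipi_angle = c(60, 90),
                            pialkyl_max = 5.5, his_positive = FALSE) {
  stopifnot(hbond_max > 0, charge_max > 0, pipi_max > 0, pialkyl_max > 0,
            length(pipi_angle) == 2L, all(pipi_angle >= 0),
            all(pipi_angle <= 90))
  structure(list(hbond_max = hbond_max, charge_max = charge_max,
                 pipi_max = pipi_max, pipi_angle = pipi_angle,
                 pialkyl_max = pialkyl_max, his_positive = his_positive),
            class = "geometry_params")
}

RING_ATOMS <- list(
  PHE = list(ring6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring5 = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(ring5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

ALKYL_SIDE_CARBONS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"), PRO = c("CB", "CG", "CD"), CYS = "CB")

# donor heavy atoms: every nitrogen; hydroxyl oxygens; cysteine thiol
is_donor <- function(model) {
  model$element == "N" |
    (model$atom %in% c("OG", "OG1", "OH")) |
    (model$resname == "CYS" & model$atom == "SG")
}

# acceptors: every oxygen; histidine ring nitrogens
is_acceptor <- function(model) {
  model$element == "O" |
    (model$resname == "HIS" & model$atom %in% c("ND1", "NE2"))
}

positive_atoms <- function(model, his_positive = FALSE) {
  pos <- (model$resname == "ARG" & model$atom %in% c("NE", "NH1", "NH2")) |
    (model$resname == "LYS" & model$atom == "NZ")
  if (his_positive) {
    pos <- pos | (model$resname == "HIS" & model$atom %in% c("ND1", "NE2"))
  }
  pos
}

negative_atoms <- function(model) {
  neg <- (model$resname == "ASP" & model$atom %in% c("OD1", "OD2")) |
    (model$resname == "GLU" & model$atom %in% c("OE1", "OE2"))
  # C-terminal carboxylate: the OXT-bearing residue's O and OXT
  has_oxt <- model$atom == "OXT"
  if (any(has_oxt)) {
    term <- unique(model[has_oxt, c("chain", "resno")])
    for (k in seq_len(nrow(term))) {
      neg <- neg | (model$chain == term$chain[k] &
                      model$resno == term$resno[k] &
                      model$atom %in% c("O", "OXT"))
    }
  }
  neg
}

ring_geometry <- function(model, idx) {
  xyz <- as.matrix(model[idx, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  normal <- svd(centered)$v[, 3]
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

collect_rings <- function(model) {
  res <- unique(model[model$resname %in% names(RING_ATOMS),
                      c("chain", "resname", "resno")])
  rings <- list()
  for (k in seq_len(nrow(res))) {
    for (ring_name in names(RING_ATOMS[[res$resname[k]]])) {
      wanted <- RING_ATOMS[[res$resname[k]]][[ring_name]]
      idx <- which(model$chain == res$chain[k] &
                     model$resno == res$resno[k] & model$atom %in% wanted)
      if (length(idx) == length(wanted)) {
        rings[[length(rings) + 1L]] <- c(
          list(chain = res$chain[k], resname = res$resname[k],
               resno = res$resno[k]), ring_geometry(model, idx))
      }
    }
  }
  rings
}

sel_of <- function(chain, resname, resno, atom = NULL) {
  base <- sprintf("%s:%s%d", chain, resname, resno)
  if (is.null(atom)) base else paste0(base, ":", atom)
}

#' Detect typed inter-chain interactions at a two-chain interface
#'
#' Scans all cross-chain atom/group pairs between \code{chain_a} and
#' \code{chain_b} and reports four interaction types under the configured
#' geometric cutoffs: conventional hydrogen bonds (donor heavy atom N/O/S
#' to acceptor N/O), electrostatic attractive-charge contacts
#' (Arg/Lys nitrogens to Asp/Glu/C-terminal carboxylate oxygens),
#' T-shaped pi-pi ring pairs (centroid distance plus a 60-90 degree
#' inter-plane angle), and pi-alkyl contacts (ring centroid to aliphatic
#' side-chain carbon). For tryptophan both rings are measured and the
#' nearer is reported. Records are sorted by type then distance; the same
#' atom/group pair is reported once per type.
#'
#' @param model a \code{structure_model}.
#' @param chain_a,chain_b chain identifiers; both must exist in the model.
#' @param params a [geometry_params()].
#' @return data frame of interaction records: \code{type}, \code{from},
#'   \code{to}, \code{distance}, \code{from_role}, \code{to_role}.
#' @export
detect_interactions <- function(model, chain_a, chain_b,
                                params = geometry_params()) {
  for (ch in c(chain_a, chain_b)) {
    if (!any(model$chain == ch)) stop("chain absent from model: ", ch)
  }
  two <- model[model$chain %in% c(chain_a, chain_b), , drop = FALSE]
  in_a <- two$chain == chain_a
  xyz <- as.matrix(two[, c("x", "y", "z")])
  pair_dist <- function(i, j) {
    sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  }
  out <- list()
  emit <- function(type, from_i, to_i, d, roles) {
    data.frame(type = type,
               from = sel_of(two$chain[from_i], two$resname[from_i],
                             two$resno[from_i], two$atom[from_i]),
               to = sel_of(two$chain[to_i], two$resname[to_i],
                           two$resno[to_i], two$atom[to_i]),
               distance = round(d, 2), from_role = roles[1],
               to_role = roles[2], stringsAsFactors = FALSE)
  }
  cross_pairs <- function(mask_1, mask_2, cutoff) {
    # directed pairs (i from mask_1 on either chain, j on the other chain)
    i_idx <- which(mask_1); j_idx <- which(mask_2)
    if (!length(i_idx) || !length(j_idx)) return(NULL)
    grid <- expand.grid(i = i_idx, j = j_idx)
    grid <- grid[in_a[grid$i] != in_a[grid$j], , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    grid$d <- pair_dist(grid$i, grid$j)
    grid[grid$d <= cutoff + 1e-9, , drop = FALSE]
  }

  hb <- cross_pairs(is_donor(two), is_acceptor(two), params$hbond_max)
  if (!is.null(hb) && nrow(hb)) {
    hb <- hb[two$resno[hb$i] != two$resno[hb$j] |
               two$chain[hb$i] != two$chain[hb$j], , drop = FALSE]
    for (k in seq_len(nrow(hb))) {
      out[[length(out) + 1L]] <- emit("hbond", hb$i[k], hb$j[k], hb$d[k],
                                      c("donor", "acceptor"))
    }
  }

  ac <- cross_pairs(positive_atoms(two, params$his_positive),
                    negative_atoms(two), params$charge_max)
  if (!is.null(ac) && nrow(ac)) {
    for (k in seq_len(nrow(ac))) {
      out[[length(out) + 1L]] <- emit("attractive_charge", ac$i[k], ac$j[k],
                                      ac$d[k], c("positive", "negative"))
    }
  }

  rings <- collect_rings(two)
  if (length(rings)) {
    ring_chain <- vapply(rings, `[[`, character(1), "chain")
    ring_key <- vapply(rings, function(r)
      sel_of(r$chain, r$resname, r$resno), character(1))
    # pi-pi T-shaped: per residue pair keep the nearest ring combination
    best <- list()
    for (a in seq_along(rings)) for (b in seq_along(rings)) {
      if (a >= b || ring_chain[a] == ring_chain[b]) next
      ra <- rings[[a]]; rb <- rings[[b]]
      d <- sqrt(sum((ra$centroid - rb$centroid)^2))
      ang <- acos(min(1, abs(sum(ra$normal * rb$normal)))) * 180 / pi
      if (d <= params$pipi_max + 1e-9 && ang >= params$pipi_angle[1] &&
          ang <= params$pipi_angle[2]) {
        key <- paste(ring_key[a], ring_key[b])
        if (is.null(best[[key]]) || d < best[[key]]$d) {
          best[[key]] <- list(a = ra, b = rb, d = d)
        }
      }
    }
    for (hit in best) {
      # report with the chain_a partner first
      first_a <- hit$a$chain == chain_a
      fa <- if (first_a) hit$a else hit$b
      fb <- if (first_a) hit$b else hit$a
      out[[length(out) + 1L]] <- data.frame(
        type = "pi_pi_t_shaped",
        from = sel_of(fa$chain, fa$resname, fa$resno),
        to = sel_of(fb$chain, fb$resname, fb$resno),
        distance = round(hit$d, 2), from_role = "pi", to_role = "pi",
        stringsAsFactors = FALSE)
    }
    # pi-alkyl: ring centroid to aliphatic side-chain carbons
    alk <- which(two$resname %in% names(ALKYL_SIDE_CARBONS) &
                   mapply(function(rn, at) at %in% ALKYL_SIDE_CARBONS[[rn]],
                          two$resname, two$atom))
    best_alk <- list()
    for (a in seq_along(rings)) {
      ra <- rings[[a]]
      for (j in alk) {
        if (two$chain[j] == ra$chain) next
        d <- sqrt(sum((ra$centroid - xyz[j, ])^2))
        if (d <= params$pialkyl_max + 1e-9) {
          key <- paste(ring_key[a], sel_of(two$chain[j], two$resname[j],
                                           two$resno[j]))
          if (is.null(best_alk[[key]]) || d < best_alk[[key]]$d) {
            best_alk[[key]] <- list(ring = ra, j = j, d = d)
          }
        }
      }
    }
    for (hit in best_alk) {
      out[[length(out) + 1L]] <- data.frame(
        type = "pi_alkyl",
        from = sel_of(hit$ring$chain, hit$ring$resname, hit$ring$resno),
        to = sel_of(two$chain[hit$j], two$resname[hit$j], two$resno[hit$j]),
        distance = round(hit$d, 2), from_role = "pi", to_role = "alkyl",
        stringsAsFactors = FALSE)
    }
  }

  if (!length(out)) {
    return(data.frame(type = character(0), from = character(0),
                      to = character(0), distance = numeric(0),
                      from_role = character(0), to_role = character(0),
                      stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, out)
  tab <- tab[!duplicated(tab[, c("type", "from", "to")]), , drop = FALSE]
  type_order <- c("hbond", "attractive_charge", "pi_pi_t_shaped", "pi_alkyl")
  tab <- tab[order(match(tab$type, type_order), tab$distance, tab$from),
             , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write an interaction table as TSV
#'
#' Columns: Interaction (\code{from - to}), Distance_A, Type, From_role,
#' To_role. An empty record list yields a header-only file.
#'
#' @param records output of [detect_interactions()].
#' @param path output path.
#' @export
interaction_table <- function(records, path = NULL) {
  df <- data.frame(Interaction = if (nrow(records)) {
    paste(records$from, records$to, sep = " - ")
  } else character(0),
  Distance_A = records$distance, Type = records$type,
  From_role = records$from_role, To_role = records$to_role,
  stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
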