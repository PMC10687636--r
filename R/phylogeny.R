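#' Pairwise evolutionary distances from a protein alignment
#'
#' Columns where either member of a pair carries a gap are dropped for that
#' pair (pairwise deletion). Corrections: \code{p} is the raw mismatch
#' fraction; \code{poisson} is \code{-ln(1 - p)}; \code{kimura} is the
#' protein approximation \code{-ln(1 - p - 0.2 p^2)}.
#'
#' @param aln a \code{peptide_alignment} with at least two rows.
#' @param correction one of \code{"kimura"} (default), \code{"p"},
#'   \code{"poisson"}.
#' @return symmetric numeric matrix (substitutions/site) with ids as
#'   dimnames.
#' @export
pairwise_distances <- function(aln,
                               correction = c("kimura", "p", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(inherits(aln, "peptide_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("need at least two sequences")
  m <- as.matrix(aln)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) stop("no comparable columns for pair ", aln$ids[i], " / ",
                       aln$ids[j])
    p <- mean(m[i, ok] != m[j, ok])
    v <- switch(correction,
      p = p,
      poisson = {
        if (p >= 1) stop("p = 1 out of poisson domain for pair ",
                         aln$ids[i], " / ", aln$ids[j])
        -log(1 - p)
      },
      kimura = {
        if (1 - p - 0.2 * p^2 <= 0) {
          stop("p out of kimura domain for pair ", aln$ids[i], " / ",
               aln$ids[j])
        }
        -log(1 - p - 0.2 * p^2)
      })
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining with deterministic tie-breaking
#' (the smallest index pair wins on equal Q) and negative branch lengths
#' clamped to zero. Exact on additive (tree-metric) matrices. Three taxa
#' resolve by the three-point formulas.
#'
#' @param dm symmetric distance matrix with ids as dimnames (n >= 3).
#' @return an unrooted \code{ape::phylo} tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- sprintf("t%d", seq_len(n))
  stopifnot(isTRUE(all.equal(dm, t(dm))), all(is.finite(dm)))

  # grow an edge list over node ids: 1..n leaves, n+1.. internal
  next_node <- n + 1L
  active <- seq_len(n)        # node ids of current clusters
  D <- dm
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  while (length(active) > 3L) {
    r <- length(active)
    sums <- rowSums(D)
    Q <- (r - 2) * D - outer(sums, sums, `+`)
    diag(Q) <- Inf
    # smallest Q; ties to the smallest (i, j) index pair, column-major on
    # the upper triangle scanned row-first
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- 0.5 * D[i, j] + (sums[i] - sums[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    edges <- rbind(edges, c(next_node, active[i]), c(next_node, active[j]))
    lens <- c(lens, max(0, li), max(0, lj))
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    D <- rbind(cbind(D, newd), c(newd, 0))
    keep <- setdiff(seq_len(r + 1L), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    active <- c(active, next_node)[keep]
    next_node <- next_node + 1L
  }
  # closing 3-star: three-point formulas
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  edges <- rbind(edges, c(next_node, active[1]), c(next_node, active[2]),
                 c(next_node, active[3]))
  lens <- c(lens, max(0, l1), max(0, l2), max(0, l3))

  # renumber to ape convention: leaves 1..n, root = n+1, internals follow
  internal_old <- sort(unique(edges[, 1]))
  root_old <- next_node
  internal_old <- c(root_old, setdiff(internal_old, root_old))
  map <- integer(max(edges))
  map[seq_len(n)] <- seq_len(n)
  map[internal_old] <- n + seq_along(internal_old)
  tree <- list(edge = cbind(map[edges[, 1]], map[edges[, 2]]),
               edge.length = lens, tip.label = ids,
               Nnode = length(internal_old))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  tree
}

# leaf-id bipartition keys for each internal edge of an unrooted tree;
# canonical side = the side not containing tip 1
bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  for (p in parts) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (tree$tip.label[1] %in% side) {
      side <- sort(setdiff(tree$tip.label, side))
    }
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap supports for the neighbor-joining tree of an alignment
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement \code{n_reps} times, rebuilds the tree each time, and
#' scores every internal bipartition of the full-data tree by the
#' percentage of replicates containing it. Fully reproducible from
#' \code{seed}. Replicates whose resampled matrix is degenerate (a
#' distance-correction domain error or an incomparable pair) are skipped
#' and counted.
#'
#' @param aln a \code{peptide_alignment}.
#' @param n_reps number of bootstrap replicates (>= 1; the reference
#'   protocol uses 1,000).
#' @param seed integer seed.
#' @param correction distance correction, see [pairwise_distances()].
#' @return the full-data \code{phylo} tree with \code{node.label} holding
#'   integer supports in [0, 100] on internal nodes (root label empty) and
#'   attributes \code{supports} (named vector keyed by bipartition) and
#'   \code{skipped_replicates}.
#' @export
bootstrap_supports <- function(aln, n_reps = 1000L, seed = 1L,
                               correction = "kimura") {
  stopifnot(n_reps >= 1L)
  full <- nj_tree(pairwise_distances(aln, correction))
  keys <- bipartitions(full)
  counts <- setNames(numeric(length(keys)), keys)
  m <- as.matrix(aln)
  skipped <- 0L
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    baln <- peptide_alignment(aln$ids,
                              apply(m[, cols, drop = FALSE], 1L, paste,
                                    collapse = ""))
    bt <- tryCatch(nj_tree(pairwise_distances(baln, correction)),
                   error = function(e) NULL)
    if (is.null(bt)) { skipped <- skipped + 1L; next }
    hit <- keys %in% bipartitions(bt)
    counts[hit] <- counts[hit] + 1
  }
  used <- n_reps - skipped
  supports <- if (used > 0) round(100 * counts / used) else counts * NA
  # attach as node labels: find, for each internal node, its bipartition
  n <- length(full$tip.label)
  node_lab <- character(full$Nnode)
  for (node in (n + 1L):(n + full$Nnode)) {
    tips <- sort(full$tip.label[unlist(ape::prop.part(full)[node - n])])
    if (full$tip.label[1] %in% tips) {
      tips <- sort(setdiff(full$tip.label, tips))
    }
    key <- paste(tips, collapse = "|")
    node_lab[node - n] <- if (key %in% names(supports)) {
      as.character(as.integer(supports[key]))
    } else ""
  }
  full$node.label <- node_lab
  attr(full, "supports") <- supports
  attr(full, "skipped_replicates") <- skipped
  full
}

#' Serialize a tree as Newick text
#'
#' Branch lengths are kept; bootstrap supports travel as internal node
#' labels. Round-trips through [read_newick()].
#'
#' @param tree an \code{ape::phylo} tree.
#' @param path optional output file.
#' @return the Newick string, invisibly when \code{path} is given.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#' @param text_or_path Newick text or a file path.
#' @export
read_newick <- function(text_or_path) {
  if (file.exists(text_or_path)) {
    ape::read.tree(text_or_path)
  } else {
    ape::read.tree(text = text_or_path)
  }
}

#' Write bipartition supports as TSV
#' @param tree output of [bootstrap_supports()].
#' @param path output path; columns \code{bipartition}, \code{support}.
#' @export
write_supports_tsv <- function(tree, path) {
  sup <- attr(tree, "supports")
  utils::write.table(
    data.frame(bipartition = names(sup), support = as.numeric(sup),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
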