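test_that("pairwise distances: identity, p, and closed-form corrections", {
  aln <- peptide_alignment(c("a", "b", "c"),
                           c("AAAAAAAAAA", "AAAAAAAAAA", "CCAAAAAAAA"))
  d_p <- pairwise_distances(aln, "p")
  expect_equal(d_p["a", "b"], 0)
  expect_equal(d_p["a", "c"], 0.2)
  expect_equal(pairwise_distances(aln, "poisson")["a", "c"], -log(0.8))
  expect_equal(pairwise_distances(aln, "kimura")["a", "c"],
               -log(1 - 0.2 - 0.2 * 0.04))
  expect_true(isSymmetric(d_p))
})

test_that("kimura correction: p = 0.5 closed form and domain errors", {
  aln <- peptide_alignment(c("a", "b"), c("AACC", "AAGG"))  # p = 0.5
  expect_equal(pairwise_distances(aln, "kimura")["a", "b"],
               -log(1 - 0.5 - 0.2 * 0.25))
  far <- peptide_alignment(c("a", "b"), c("AAAA", "CCCC"))  # p = 1
  expect_error(pairwise_distances(far, "kimura"), "domain.*a / b")
  expect_error(pairwise_distances(far, "poisson"), "domain|poisson")
  gap <- peptide_alignment(c("a", "b"), c("A---", "-CCC"))
  expect_error(pairwise_distances(gap, "p"), "no comparable")
})

test_that("distances increase strictly with p on the valid domain", {
  p <- seq(0, 0.8, by = 0.05)
  for (fun in list(function(p) -log(1 - p),
                   function(p) -log(1 - p - 0.2 * p^2))) {
    expect_true(all(diff(fun(p)) > 0))
  }
  # gap columns are deleted pairwise, not globally
  aln <- peptide_alignment(c("a", "b", "c"),
                           c("AAAA", "AA-A", "CAAA"))
  d <- pairwise_distances(aln, "p")
  expect_equal(d["a", "b"], 0)
  expect_equal(d["b", "c"], 1 / 3)
})

test_that("NJ recovers the 4-taxon additive tree exactly", {
  dm <- additive_4taxon_dm()
  tree <- nj_tree(dm)
  expect_equal(sort(tree$tip.label), LETTERS[1:4])
  expect_setequal(tree_cherry_keys(tree), exhaustive_cherry_oracle(dm))
  # branch lengths: pairwise tree distances reproduce the input metric
  cop <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cop, dm, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("NJ recovers 5-taxon additive trees against the oracle", {
  # ((A:1,B:2):2,(C:1.5,D:2.5):1.5,E:6)
  tr_txt <- "((A:1,B:2):2,(C:1.5,D:2.5):1.5,E:6);"
  ref <- ape::read.tree(text = tr_txt)
  dm <- ape::cophenetic.phylo(ref)[LETTERS[1:5], LETTERS[1:5]]
  tree <- nj_tree(dm)
  expect_setequal(tree_cherry_keys(tree), exhaustive_cherry_oracle(dm))
  cop <- ape::cophenetic.phylo(tree)[LETTERS[1:5], LETTERS[1:5]]
  expect_equal(cop, dm, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("3 taxa resolve by the three-point formulas", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(dm)
  len <- setNames(tree$edge.length[match(seq_len(3), tree$edge[, 2])],
                  tree$tip.label)
  expect_equal(len[["A"]], 1)  # (3 + 4 - 5) / 2
  expect_equal(len[["B"]], 2)
  expect_equal(len[["C"]], 3)
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ topology is invariant under taxon permutation", {
  dm <- additive_4taxon_dm()
  perm <- c(3, 1, 4, 2)
  tree_p <- nj_tree(dm[perm, perm])
  expect_setequal(tree_cherry_keys(tree_p),
                  tree_cherry_keys(nj_tree(dm)))
})

test_that("NJ agrees with the ape reference implementation on noisy data", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 8
    base <- matrix(runif(n * n, 0.1, 1), n, n)
    dm <- (base + t(base)) / 2
    diag(dm) <- 0
    dimnames(dm) <- list(letters[1:n], letters[1:n])
    mine <- nj_tree(dm)
    ref <- ape::nj(dm)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports: determinism, bounds, and n_reps = 1", {
  fam <- generate_family(synthetic_config(n_sequences = 8, seed = 14,
                                          substitution_noise = 0.4))
  b1 <- bootstrap_supports(fam$aln, n_reps = 20, seed = 99)
  b2 <- bootstrap_supports(fam$aln, n_reps = 20, seed = 99)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
  expect_true(all(attr(b1, "supports") >= 0 & attr(b1, "supports") <= 100))

  single <- bootstrap_supports(fam$aln, n_reps = 1, seed = 3)
  sup <- attr(single, "supports")
  skipped <- attr(single, "skipped_replicates")
  if (skipped == 0) expect_true(all(sup %in% c(0, 100)))
})

test_that("a planted bipartition between two clusters gets full support", {
  # two 5-leaf clusters separated by many fixed differences
  set.seed(1)
  core_a <- paste(sample(AA_STANDARD, 60, replace = TRUE), collapse = "")
  core_b <- {
    ch <- strsplit(core_a, "")[[1]]
    flip <- seq(1, 60, by = 2)  # 50% divergence between clusters
    ch[flip] <- vapply(ch[flip], function(a) {
      sample(setdiff(AA_STANDARD, a), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  mutate_few <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    ch[idx] <- vapply(ch[idx], function(a) {
      sample(setdiff(AA_STANDARD, a), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  seqs <- c(vapply(1:5, function(i) mutate_few(core_a, 2, i), character(1)),
            vapply(1:5, function(i) mutate_few(core_b, 2, 100 + i),
                   character(1)))
  aln <- peptide_alignment(c(paste0("a", 1:5), paste0("b", 1:5)), seqs)
  tree <- bootstrap_supports(aln, n_reps = 100, seed = 7)
  sup <- attr(tree, "supports")
  split_key <- names(sup)[vapply(names(sup), function(k) {
    setequal(strsplit(k, "|", fixed = TRUE)[[1]], paste0("b", 1:5)) ||
      setequal(strsplit(k, "|", fixed = TRUE)[[1]], paste0("a", 1:5))
  }, logical(1))]
  expect_length(split_key, 1)
  expect_equal(unname(sup[split_key]), 100)
})

test_that("newick writing round-trips with supports as node labels", {
  fam <- generate_family(synthetic_config(n_sequences = 6, seed = 2,
                                          substitution_noise = 0.4))
  tree <- bootstrap_supports(fam$aln, n_reps = 10, seed = 5)
  txt <- write_newick(tree)
  back <- read_newick(txt)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  expect_equal(back$edge.length[order(back$edge.length)],
               tree$edge.length[order(tree$edge.length)], tolerance = 1e-8)
  labs <- setdiff(back$node.label, "")
  expect_true(all(grepl("^\\d+$", labs)))

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  expect_identical(readLines(f), txt)
})
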