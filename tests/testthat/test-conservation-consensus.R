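aln4 <- peptide_alignment(
  c("s1", "s2", "s3", "s4"),
  c("CSCA", "CSCK", "CSCD", "C-TR"))

test_that("column frequencies use the row count as denominator", {
  f <- column_frequencies(aln4)
  expect_equal(colSums(f), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unname(f["C", 1]), 1)
  expect_equal(unname(f["S", 2]), 0.75)
  expect_equal(unname(f["-", 2]), 0.25)
  expect_equal(unname(f["C", 3]), 0.75)
  expect_error(column_frequencies(peptide_alignment("a", "AB!")),
               "unknown residue|unequal")
})

test_that("threshold consensus: identity beats class; classes by scheme order", {
  # column of S,T,S,S: identity S at 70 (75% >= 70); class o at 90
  aln <- peptide_alignment(paste0("r", 1:4), c("S", "T", "S", "S"))
  expect_equal(consensus_at_threshold(aln, 70), "S")
  expect_equal(consensus_at_threshold(aln, 90), "o")
  expect_equal(consensus_at_threshold(aln, 100), "o")

  all_c <- peptide_alignment(paste0("r", 1:4), rep("C", 4))
  expect_equal(consensus_at_threshold(all_c, 100), "C")

  # A,K,D,R: only the broad turnlike class covers all four (100% >= 90)
  mixed <- peptide_alignment(paste0("r", 1:4), c("A", "K", "D", "R"))
  expect_equal(consensus_at_threshold(mixed, 90), "t")
  narrow <- residue_class_scheme(list(h = c("A", "L", "V"), o = c("S", "T")))
  expect_true(is.na(consensus_at_threshold(mixed, 90, narrow)))
})

test_that("gaps count against the threshold", {
  aln <- peptide_alignment(paste0("r", 1:4), c("C", "C", "C", "-"))
  expect_equal(consensus_at_threshold(aln, 70), "C")
  expect_true(is.na(consensus_at_threshold(aln, 90)))
})

test_that("calls are monotone in the threshold", {
  for (seed in 1:4) {
    fam <- generate_family(synthetic_config(n_sequences = 12, seed = seed,
                                            substitution_noise = 0.3))
    prof <- consensus_profile(fam$aln, thresholds = c(100, 90, 80, 70))
    called <- !is.na(prof$calls)
    for (i in seq_len(nrow(called) - 1L)) {
      # every column called at the higher threshold stays called below it
      expect_true(all(called[i + 1, ] >= called[i, ]))
    }
    # identity calls persist downward as the same letter
    for (col in which(prof$calls["100%", ] %in% AA_STANDARD)) {
      expect_equal(unname(prof$calls["70%", col]),
                   unname(prof$calls["100%", col]))
    }
  }
})

test_that("derive_spacing_motif recovers the generator scaffold", {
  fam <- generate_family(synthetic_config(n_sequences = 30, seed = 11,
                                          violation_rate = 0))
  m <- derive_spacing_motif(fam$aln)
  expect_equal(format(m), "CXXXCXXXXDCXXXXXCXXC")
  expect_equal(format(m, style = "prosite"),
               "C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C")
})

test_that("derived spacers are the modal inter-anchor counts", {
  # 10 rows; spacer-1 length 3 in 6 rows and 4 (via a gap column) in 4 rows
  with_gap <- "CAAGAC" # spacer 4
  no_gap <- "CAA-GC"   # spacer 3 after degapping
  seqs <- c(rep(no_gap, 6), rep(with_gap, 4))
  aln <- peptide_alignment(sprintf("r%02d", 1:10), seqs)
  m <- derive_spacing_motif(
    peptide_alignment(aln$ids, paste0(seqs, "AAACAAAADCAAAAACAAC")),
    anchor_threshold = 90)
  expect_equal(m$spacers[1], 3L)
})

test_that("derive errors without five conserved cysteine columns", {
  aln <- peptide_alignment(c("a", "b"), c("CAAAC", "CAAAC"))
  expect_error(derive_spacing_motif(aln), "scaffold not found")
})

test_that("scan_motif handles literal hits, violations and overlaps", {
  expect_equal(scan_motif("CAAACAAAADCAAAAACAAC"), 1L)
  expect_equal(scan_motif("CAAACAAAAECAAAAACAAC"), integer(0))
  expect_equal(scan_motif("XXCAAACAAAADCAAAAACAAC"), 3L)
  # overlapping matches of a short custom motif
  m <- spacing_motif(c("C", "C"), 1L)
  expect_equal(scan_motif("CACAC", m), c(1L, 3L))
  expect_error(scan_motif("CA-AC", m), "ungapped")
})

test_that("scan_motif agrees with the regex oracle on random sequences", {
  seqs <- random_peptides(20, 500, seed = 42)
  for (s in seqs) {
    expect_identical(scan_motif(s), regex_scan_oracle(s))
    # also under a denser motif that actually fires at this length
    m <- spacing_motif(c("C", "A"), 2L)
    expect_identical(scan_motif(s, m), regex_scan_oracle(s, m))
  }
})

test_that("motif_match_rate counts matching records", {
  clean <- generate_family(synthetic_config(n_sequences = 10, seed = 5))
  expect_equal(motif_match_rate(clean$records), 100)
  decoys <- generate_decoys(10, seed = 5)
  expect_equal(motif_match_rate(decoys), 0)
  both <- rbind(clean$records[1:9, ], decoys[1, ])
  expect_equal(motif_match_rate(both), 90)
  expect_error(motif_match_rate(clean$records[0, ]), "no records")
})

test_that("consensus TSV writers produce well-formed tables", {
  fam <- generate_family(synthetic_config(n_sequences = 8, seed = 2))
  prof <- consensus_profile(fam$aln)
  calls_f <- withr::local_tempfile(fileext = ".tsv")
  freqs_f <- withr::local_tempfile(fileext = ".tsv")
  write_consensus_tsv(prof, calls_f, freqs_f)
  calls <- read.delim(calls_f)
  expect_equal(nrow(calls), fam$aln$ncol)
  freqs <- read.delim(freqs_f, check.names = FALSE)
  expect_equal(nrow(freqs), 21)  # 20 residues + gap
  expect_equal(colSums(freqs[, -1]), rep(1, fam$aln$ncol),
               ignore_attr = TRUE)
})
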