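test_that("parse_structure reads minimal PDB text", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_text(fixture_charge(), f)
  m <- parse_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$resname, c("ARG", "ASP"))
  expect_equal(m$x, c(0, 4))
  expect_equal(m$element, c("N", "O"))
})

test_that("multi-model files contribute model 1 only", {
  f <- withr::local_tempfile(fileext = ".pdb")
  one <- fixture_charge()
  lines1 <- readLines(write_pdb_text(one, withr::local_tempfile()))
  shifted <- one; shifted$x <- shifted$x + 50
  lines2 <- readLines(write_pdb_text(shifted, withr::local_tempfile()))
  writeLines(c("MODEL     1", head(lines1, -1), "ENDMDL",
               "MODEL     2", head(lines2, -1), "ENDMDL", "END"), f)
  m <- parse_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(max(m$x), 4)
})

test_that("altloc duplicates resolve by occupancy then altloc A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ALEU A  10      1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BLEU A  10      2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB ALEU A  10      3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BLEU A  10      4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- parse_structure(f)
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$atom == "CA"], 2)  # higher occupancy wins
  expect_equal(m$x[m$atom == "CB"], 3)  # tie -> altloc A
})

test_that("parse errors name the offending condition", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TEST", "END"), f)
  expect_error(parse_structure(f), "no ATOM")
  writeLines(c("ATOM      1  CA  LEU A  10      xxx.00   0.000   0.000"), f)
  expect_error(parse_structure(f), "line 1")
})

test_that("atom_distance is Euclidean to 2 decimals", {
  m <- structure_model(chain = c("A", "B", "B"),
                       resname = c("GLY", "GLY", "GLY"),
                       resno = c(1, 2, 3), atom = c("CA", "CA", "CA"),
                       x = c(0, 3, 0), y = c(0, 4, 0), z = c(0, 0, 0))
  expect_equal(atom_distance(m, "A:GLY1:CA", "B:GLY2:CA"), 5)
  expect_equal(atom_distance(m, "A:GLY1:CA", "B:GLY3:CA"), 0)
  expect_error(atom_distance(m, "A:GLY9:CA", "B:GLY2:CA"),
               "A:GLY9:CA")
})

test_that("each single-interaction fixture yields exactly its one record", {
  cases <- list(hbond = fixture_hbond(),
                attractive_charge = fixture_charge(),
                pi_pi_t_shaped = fixture_pipi(),
                pi_alkyl = fixture_pialkyl())
  for (type in names(cases)) {
    rec <- detect_interactions(cases[[type]], "A", "B")
    expect_equal(nrow(rec), 1, info = type)
    expect_equal(rec$type, type)
  }
  rec <- detect_interactions(fixture_hbond(), "A", "B")
  expect_equal(rec$distance, 2.9)
  expect_equal(c(rec$from_role, rec$to_role), c("donor", "acceptor"))
})

test_that("pi-pi centroid distance matches the hand-built geometry", {
  rec <- detect_interactions(fixture_pipi(), "A", "B")
  expect_equal(rec$distance, 5.00)
  expect_equal(rec$from, "A:PHE30")
  expect_equal(rec$to, "B:PHE40")
})

test_that("detection is invariant under rigid motion", {
  combined <- rbind_models(fixture_hbond(), fixture_charge(),
                           fixture_pipi(), fixture_pialkyl())
  # make residue numbers unique across the stacked fixtures
  base <- detect_interactions(combined, "A", "B")
  expect_equal(sort(unique(base$type)),
               sort(c("hbond", "attractive_charge", "pi_pi_t_shaped",
                      "pi_alkyl")))
  for (seed in 1:3) {
    moved <- rigid_transform(combined, seed = seed)
    got <- detect_interactions(moved, "A", "B")
    expect_equal(got[, c("type", "from", "to", "distance")],
                 base[, c("type", "from", "to", "distance")])
  }
})

test_that("all reported distances respect their cutoffs", {
  params <- geometry_params()
  combined <- rbind_models(fixture_hbond(), fixture_charge(),
                           fixture_pipi(), fixture_pialkyl())
  rec <- detect_interactions(combined, "A", "B", params)
  caps <- c(hbond = params$hbond_max,
            attractive_charge = params$charge_max,
            pi_pi_t_shaped = params$pipi_max,
            pi_alkyl = params$pialkyl_max)
  expect_true(all(rec$distance <= caps[rec$type] + 1e-9))
  expect_true(all(rec$distance > 0))
  # tightening the cutoffs below the fixture distances silences them
  tight <- geometry_params(hbond_max = 1, charge_max = 1, pipi_max = 1,
                           pialkyl_max = 1)
  expect_equal(nrow(detect_interactions(combined, "A", "B", tight)), 0)
})

test_that("parallel rings are not T-shaped; angle window is honored", {
  parallel <- rbind_models(
    phe_ring_model("A", 30, c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    phe_ring_model("B", 40, c(0, 0, 5), c(1, 0, 0), c(0, 1, 0)))
  rec <- detect_interactions(parallel, "A", "B")
  expect_false("pi_pi_t_shaped" %in% rec$type)
})

test_that("absent chains raise an error", {
  expect_error(detect_interactions(fixture_hbond(), "A", "Z"),
               "chain absent")
})

test_that("interaction_table serializes with the documented columns", {
  rec <- detect_interactions(fixture_charge(), "A", "B")
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- interaction_table(rec, f)
  expect_equal(names(tab), c("Interaction", "Distance_A", "Type",
                             "From_role", "To_role"))
  expect_match(tab$Interaction, "A:ARG10:NH1 - B:ASP5:OD1")
  empty <- interaction_table(rec[0, ], withr::local_tempfile())
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(read.delim(f)), 1)
})
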