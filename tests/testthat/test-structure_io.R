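test_that("PDB parsing maps residues, elements and CA confidences", {
  s <- read_structure(two_residue_pdb(95, 60), id = "toy")
  expect_s3_class(s, "protein_structure")
  expect_equal(s$sequence, "AG")
  expect_equal(nrow(s$atoms), 9)
  conf <- tapply(s$atoms$confidence, s$atoms$residue_index, unique)
  expect_equal(as.numeric(conf), c(95, 60))
  expect_equal(sum(s$atoms$atom_name == "CA"), 2)
})

test_that("waters, hydrogens and missing-CA residues are handled", {
  atoms <- data.frame(
    type = c("ATOM", "ATOM", "HETATM", "ATOM"),
    name = c("CA", "HB1", "O", "N"),
    resid = c("ALA", "ALA", "HOH", "GLY"),
    resno = c(1L, 1L, 90L, 2L),
    x = c(0, 1, 8, 3), y = c(0, 1, 8, 3), z = c(0, 1, 8, 3),
    b = c(80, 80, 0, 70),
    elem = c("C", "H", "O", "N"), stringsAsFactors = FALSE)
  expect_warning(s <- read_structure(make_pdb_text(atoms)),
                 "without a CA")
  # water and hydrogen gone; residue 2 dropped (no CA)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$atom_name, "CA")
})

test_that("empty input errors", {
  expect_error(read_structure("END"), "no atoms")
})

test_that("atom selectors pick the documented point sets", {
  s <- read_structure(two_residue_pdb(), id = "toy")
  expect_equal(extract_point_cloud(s, "CA")$n, 2)
  expect_equal(extract_point_cloud(s, "ALL_ATOMS")$n, 9)
  expect_equal(extract_point_cloud(s, "ALL_N")$n, 2)
  expect_equal(extract_point_cloud(s, "ALL_O")$n, 2)
  # ALA contributes CA, C, CB; GLY contributes CA, C
  expect_equal(extract_point_cloud(s, "ALL_C")$n, 5)
  expect_equal(extract_point_cloud(s, "ALL_C", sidechain_only = TRUE)$n, 1)
  pc <- extract_point_cloud(s, "CA")
  ca <- s$atoms[s$atoms$atom_name == "CA", ]
  expect_equal(pc$points, unname(as.matrix(ca[, c("x", "y", "z")])))
  # every selector cloud is a subset of ALL_ATOMS
  all_pts <- extract_point_cloud(s, "ALL_ATOMS")$points
  for (sel in c("CA", "ALL_C", "ALL_N", "ALL_O")) {
    p <- extract_point_cloud(s, sel)$points
    expect_true(all(apply(p, 1, function(row)
      any(colSums(abs(t(all_pts) - row)) < 1e-12))))
  }
})

test_that("confidence masking keeps residues at or above the threshold", {
  pdb <- make_pdb_text(data.frame(
    type = "ATOM", name = "CA", resid = "ALA", resno = 1:3,
    x = c(0, 3.8, 7.6), y = 0, z = 0, b = c(95, 60, 80), elem = "C",
    stringsAsFactors = FALSE))
  s <- read_structure(pdb)
  pc <- extract_point_cloud(s, "CA")
  kept <- mask_low_confidence(pc, s, 70)
  expect_equal(kept$residue_of_point, c(1, 3))
  expect_equal(mask_low_confidence(pc, s, 0)$n, 3)
  # strict comparison drops the boundary residue
  s2 <- s; s2$atoms$confidence <- c(95, 70, 80)
  expect_equal(mask_low_confidence(pc, s2, 70)$n, 3)
  expect_equal(mask_low_confidence(pc, s2, 70, strict = TRUE)$n, 2)
  s3 <- s; s3$atoms$confidence <- rep(50, 3)
  expect_error(mask_low_confidence(pc, s3, 70), "empty cloud")
})

test_that("pair-specific indel masking removes opposing residues", {
  aln <- toy_alignment(c(A = "ACDE", B = "A-DE"))
  pm <- pair_indel_map(aln, "A", "B")
  mk_structure <- function(n) {
    read_structure(make_pdb_text(data.frame(
      type = "ATOM", name = "CA", resid = "ALA", resno = seq_len(n),
      x = 3.8 * seq_len(n), y = 0, z = 0, b = 90, elem = "C",
      stringsAsFactors = FALSE)))
  }
  pcA <- extract_point_cloud(mk_structure(4), "CA")
  pcB <- extract_point_cloud(mk_structure(3), "CA")
  mk <- mask_indel_residues(pcA, pcB, pm)
  expect_equal(mk$A$residue_of_point, c(1, 3, 4))
  expect_equal(mk$B$n, 3)
  # gapless pair: no-op
  aln2 <- toy_alignment(c(A = "ACDE", B = "ACDF"))
  mk2 <- mask_indel_residues(pcA, pcA, pair_indel_map(aln2, "A", "B"))
  expect_equal(mk2$A$n, 4)
  # mask referring to residues the structure does not have
  aln3 <- toy_alignment(c(A = "ACDEFGH", B = "ACDE---"))
  pm3 <- pair_indel_map(aln3, "A", "B")
  expect_error(mask_indel_residues(pcA, pcB, pm3), "absent")
})

test_that("CI and indel masking commute as set intersection", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 40, seed = 5,
                                 indel_rate = 2, low_ci_fraction = 0.3)
  fam <- simulate_family(cfg)
  ids <- names(fam$structures)[1:2]
  sA <- fam$structures[[ids[1]]]; sB <- fam$structures[[ids[2]]]
  pm <- pair_indel_map(fam$alignment, ids[1], ids[2])
  pcA <- extract_point_cloud(sA); pcB <- extract_point_cloud(sB)
  ci_first <- mask_indel_residues(mask_low_confidence(pcA, sA, 70),
                                  mask_low_confidence(pcB, sB, 70), pm)
  both <- mask_indel_residues(pcA, pcB, pm)
  indel_first <- list(A = mask_low_confidence(both$A, sA, 70),
                      B = mask_low_confidence(both$B, sB, 70))
  expect_equal(ci_first$A$residue_of_point, indel_first$A$residue_of_point)
  expect_equal(ci_first$B$residue_of_point, indel_first$B$residue_of_point)
  # idempotence
  again <- mask_indel_residues(ci_first$A, ci_first$B, pm)
  expect_equal(again$A$residue_of_point, ci_first$A$residue_of_point)
})
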