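test_that("aligned FASTA parsing validates and normalizes", {
  m <- toy_alignment(c(s1 = "ACDE", s2 = "ACDF"))
  expect_equal(m$ncol, 4)
  expect_equal(m$ids, c("s1", "s2"))
  m2 <- toy_alignment(c(a = "acde", b = "a-de"))
  expect_equal(unname(m2$rows["a"]), "ACDE")
  expect_error(toy_alignment(c(a = "ACDE", b = "ACDEF")), "ragged")
  expect_error(toy_alignment(c(a = "ACDE", a = "ACDF")), "duplicate")
  expect_error(read_alignment(">only\nACDE"), "at least 2")
})

test_that("p-distance uses pairwise deletion of gapped columns", {
  m <- toy_alignment(c(a = "ACDE", b = "ACDF", c = "AC-E", d = "ACGE"))
  expect_equal(p_distance(m, "a", "b"), 0.25)
  expect_equal(p_distance(m, "c", "d"), 0)
  expect_equal(p_distance(m, "a", "a"), 0)
  expect_equal(p_distance(m, "a", "c"), p_distance(m, "c", "a"))
  m2 <- toy_alignment(c(a = "AC--", b = "--DE"))
  expect_error(p_distance(m2, "a", "b"), "no overlapping sites")
  # column-wise oracle on a random alignment
  with_seed(31, {
    letters20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
    rows <- vapply(1:4, function(i)
      paste(sample(c(letters20, "-"), 60, replace = TRUE,
                   prob = c(rep(1, 20), 4)), collapse = ""), character(1))
    names(rows) <- paste0("r", 1:4)
    m3 <- toy_alignment(rows)
    a <- strsplit(rows[1], "")[[1]]; b <- strsplit(rows[2], "")[[1]]
    keep <- a != "-" & b != "-"
    expect_equal(p_distance(m3, "r1", "r2"), mean(a[keep] != b[keep]))
    expect_gte(p_distance(m3, "r3", "r4"), 0)
    expect_lte(p_distance(m3, "r3", "r4"), 1)
  })
})

test_that("pair indel maps record opposing residues and ignore shared gaps", {
  m <- toy_alignment(c(A = "ACDE", B = "A-DE"))
  pm <- pair_indel_map(m, "A", "B")
  expect_equal(pm$residues_to_mask_A, 2)
  expect_length(pm$residues_to_mask_B, 0)
  expect_equal(pm$gap_count, 1)
  m2 <- toy_alignment(c(A = "A--E", B = "AGGE"))
  pm2 <- pair_indel_map(m2, "A", "B")
  expect_equal(pm2$residues_to_mask_B, c(2, 3))
  m3 <- toy_alignment(c(A = "A-E", B = "A-E"))
  pm3 <- pair_indel_map(m3, "A", "B")
  expect_length(pm3$residues_to_mask_A, 0)
  expect_length(pm3$residues_to_mask_B, 0)
  expect_equal(pm3$gap_count, 0)
})

test_that("every alignment column is accounted for by the indel map", {
  with_seed(32, {
    for (rep in 1:10) {
      letters20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
      rows <- vapply(1:2, function(i)
        paste(sample(c(letters20, "-"), 40, replace = TRUE,
                     prob = c(rep(1, 20), 5)), collapse = ""), character(1))
      names(rows) <- c("x", "y")
      m <- toy_alignment(rows)
      pm <- pair_indel_map(m, "x", "y")
      a <- strsplit(rows[1], "")[[1]]; b <- strsplit(rows[2], "")[[1]]
      comparable <- sum(a != "-" & b != "-")
      both_gap <- sum(a == "-" & b == "-")
      expect_equal(length(pm$residues_to_mask_A) +
                   length(pm$residues_to_mask_B) + comparable + both_gap, 40)
      expect_equal(pm$gap_count, 40 - comparable - both_gap)
    }
  })
})

test_that("Newick parsing demands branch lengths and two leaves", {
  tr <- read_newick("((A:1,B:2):1,C:3);")
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 3)
  expect_error(read_newick("((A,B),C);"), "branch lengths")
  expect_error(read_newick("A:1;"), "fewer than 2|parenthe|malformed")
  expect_error(read_newick("not a tree (("), "malformed|parenthe")
})

test_that("patristic matrices are path sums on the tree", {
  d <- patristic_matrix(read_newick("((A:1,B:2):1,C:3);"))
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 5)
  expect_equal(d["B", "C"], 6)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))
  star <- patristic_matrix(read_newick("(A:1,B:1,C:1,D:1);"))
  expect_true(all(star[upper.tri(star)] == 2))
})

test_that("patristic matrices satisfy the four-point condition", {
  tr <- simulate_tree(9, 2, seed = 33)
  d <- patristic_matrix(tr)
  expect_equal(d, t(d))
  with_seed(34, {
    for (rep in 1:20) {
      q <- sample(rownames(d), 4)
      s1 <- d[q[1], q[2]] + d[q[3], q[4]]
      s2 <- d[q[1], q[3]] + d[q[2], q[4]]
      s3 <- d[q[1], q[4]] + d[q[2], q[3]]
      sums <- sort(c(s1, s2, s3))
      expect_lt(abs(sums[3] - sums[2]), 1e-9) # two largest sums equal
    }
  })
})
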