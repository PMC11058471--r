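test_that("Yule trees have the right shape and are reproducible", {
  tr <- simulate_tree(7, 2, seed = 1)
  expect_length(tr$tip.label, 7)
  expect_equal(nrow(tr$edge), 2 * 7 - 2)
  expect_true(all(tr$edge.length >= 0))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(7, 2, seed = 1)))
  expect_error(simulate_tree(5, 2), ">= 7")
  # total length scales inversely with the birth rate (Yule expectation)
  with_seed(2, {
    len <- function(rate) mean(replicate(40, sum(simulate_tree(8, rate)$edge.length)))
    ratio <- len(0.5) / len(5)
    expect_gt(ratio, 5)
    expect_lt(ratio, 20)
  })
})

test_that("the null model produces identical sequences and structures", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 40, seed = 9,
                                 sub_rate = 0, indel_rate = 0,
                                 struct_noise_sd = 0, low_ci_fraction = 0)
  fam <- simulate_family(cfg)
  rows <- fam$alignment$rows
  expect_true(all(rows == rows[1]))
  expect_false(any(grepl("-", rows)))
  expect_equal(p_distance(fam$alignment, "t01", "t02"), 0)
  c1 <- extract_point_cloud(fam$structures$t01)$points
  c2 <- extract_point_cloud(fam$structures$t07)$points
  expect_equal(c1, c2)
  tab <- family_ph_distances(fam, metrics = c("ws", "btk"), dims = 1)
  expect_true(all(tab$raw == 0))
})

test_that("gapless evolution keeps the alignment at root length", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 45, seed = 10,
                                 indel_rate = 0)
  ev <- evolve_family(simulate_tree(7, 2, seed = 10), cfg)
  expect_equal(ev$alignment$ncol, 45)
  expect_false(any(grepl("-", ev$alignment$rows)))
})

test_that("substitutions follow the 20-state Poisson closed form", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 1000, seed = 11,
                                 indel_rate = 0, birth_rate = 1)
  tree <- simulate_tree(7, 1, seed = 11)
  ev <- evolve_family(tree, cfg)
  d <- patristic_matrix(tree)
  ids <- ev$alignment$ids
  obs <- c(); expd <- c()
  for (i in 1:6) for (j in (i + 1):7) {
    obs <- c(obs, p_distance(ev$alignment, ids[i], ids[j]))
    expd <- c(expd, (19 / 20) * (1 - exp(-(20 / 19) * d[ids[i], ids[j]])))
  }
  # binomial Monte-Carlo error at 1000 sites is below ~0.016 per pair
  expect_true(all(abs(obs - expd) < 0.05))
  expect_lt(abs(mean(obs - expd)), 0.02)
})

test_that("root backbones have exact CA spacing and structures track it", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 50, seed = 12,
                                 indel_rate = 0, struct_noise_sd = 0,
                                 low_ci_fraction = 0)
  fam <- simulate_family(cfg)
  pts <- extract_point_cloud(fam$structures$t01)$points
  spacing <- sqrt(rowSums(diff(pts)^2))
  expect_equal(spacing, rep(3.8, nrow(pts) - 1), tolerance = 1e-9)
})

test_that("coordinate divergence matches the Brownian variance identity", {
  cfg <- synthetic_family_config(n_taxa = 10, seq_length = 300, seed = 13,
                                 indel_rate = 0, struct_noise_sd = 0.4,
                                 low_ci_fraction = 0)
  fam <- simulate_family(cfg)
  d <- fam$truth
  ids <- names(fam$structures)
  ratio <- c()
  for (i in seq(1, 9, 2)) {
    a <- extract_point_cloud(fam$structures[[ids[i]]])$points
    b <- extract_point_cloud(fam$structures[[ids[i + 1]]])$points
    msd <- mean(rowSums((a - b)^2)) # 3D squared displacement per residue
    ratio <- c(ratio, msd / (3 * 0.4^2 * d[ids[i], ids[i + 1]]))
  }
  # expected squared 3D displacement = 3 * sd^2 * patristic distance
  expect_gt(mean(ratio), 0.7)
  expect_lt(mean(ratio), 1.3)
})

test_that("confidence assignment hits its boundary cases deterministically", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 40, seed = 14)
  fam <- simulate_family(cfg)
  s0 <- assign_confidence(fam$structures, 0, seed = 3)
  expect_true(all(vapply(s0, function(s) all(s$atoms$confidence >= 85),
                         logical(1))))
  s1 <- assign_confidence(fam$structures, 1, seed = 3)
  expect_true(all(vapply(s1, function(s) all(s$atoms$confidence < 70),
                         logical(1))))
  st <- s1[[1]]
  pc <- extract_point_cloud(st)
  expect_error(mask_low_confidence(pc, st, 70), "empty cloud")
  sA <- assign_confidence(fam$structures, 0.3, seed = 5)
  sB <- assign_confidence(fam$structures, 0.3, seed = 5)
  expect_identical(sA, sB)
  expect_error(assign_confidence(fam$structures, 1.2), "\\[0, 1\\]")
})

test_that("structure sequences equal ungapped alignment rows with indels", {
  for (seed in c(22, 23)) {
    cfg <- synthetic_family_config(n_taxa = 8, seq_length = 60, seed = seed,
                                   indel_rate = 3, indel_len_mean = 4)
    fam <- simulate_family(cfg)
    for (id in names(fam$structures)) {
      expect_identical(fam$structures[[id]]$sequence,
                       gsub("-", "", fam$alignment$rows[[id]]))
      expect_equal(nchar(fam$structures[[id]]$sequence),
                   extract_point_cloud(fam$structures[[id]])$n)
    }
    expect_true(any(grepl("-", fam$alignment$rows)))
  }
})

test_that("equal configs reproduce byte-identical families", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 40, seed = 30,
                                 indel_rate = 1)
  f1 <- simulate_family(cfg)
  f2 <- simulate_family(cfg)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(lapply(f1$structures, `[[`, "atoms"),
                   lapply(f2$structures, `[[`, "atoms"))
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
})

test_that("family bundles survive a disk round trip", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 40, seed = 31,
                                 indel_rate = 1)
  fam <- simulate_family(cfg, sidechain = TRUE)
  dir <- tempfile()
  write_family_bundle(fam, dir)
  back <- read_family_bundle(dir)
  expect_setequal(names(back$structures), names(fam$structures))
  for (id in names(fam$structures)) {
    a <- fam$structures[[id]]$atoms
    b <- back$structures[[id]]$atoms
    expect_identical(fam$structures[[id]]$sequence,
                     back$structures[[id]]$sequence)
    expect_lt(max(abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z)), 1e-3)
    expect_lt(max(abs(a$confidence - b$confidence)), 0.01)
  }
  expect_identical(back$alignment$rows, fam$alignment$rows)
  expect_equal(back$truth[rownames(fam$truth), colnames(fam$truth)],
               fam$truth, tolerance = 1e-6)
})

test_that("dummy side-chain atoms exercise the element selectors", {
  cfg <- synthetic_family_config(n_taxa = 7, seq_length = 40, seed = 32,
                                 indel_rate = 0)
  fam <- simulate_family(cfg, sidechain = TRUE)
  s <- fam$structures$t01
  n <- nchar(s$sequence)
  expect_equal(extract_point_cloud(s, "CA")$n, n)
  expect_equal(extract_point_cloud(s, "ALL_ATOMS")$n, 3 * n)
  expect_equal(extract_point_cloud(s, "ALL_C")$n, 2 * n)
  expect_equal(extract_point_cloud(s, "ALL_N")$n +
               extract_point_cloud(s, "ALL_O")$n, n)
})

test_that("structural divergence couples positively with the tree", {
  # The Brownian scale multiplies every displacement, so rank coupling is
  # scale-invariant up to saturation: the check is strong positivity at
  # both a small and a moderate noise level, pooled over three families.
  rho <- vapply(c(0.1, 0.25), function(sd0) {
    xs <- c(); ys <- c()
    for (s in 33:35) {
      cfg <- synthetic_family_config(n_taxa = 8, seq_length = 50, seed = s,
                                     indel_rate = 0, struct_noise_sd = sd0,
                                     low_ci_fraction = 0)
      fam <- simulate_family(cfg)
      tab <- family_ph_distances(fam, metrics = "ws", dims = 1)
      xs <- c(xs, fam$truth[cbind(tab$idA, tab$idB)])
      ys <- c(ys, tab$raw)
    }
    cor(xs, ys, method = "spearman")
  }, numeric(1))
  expect_gt(rho[1], 0.3)
  expect_gt(rho[2], 0.3)
})
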