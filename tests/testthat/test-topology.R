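unit_square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
regular_tetrahedron <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                             c(0.5, sqrt(3) / 6, sqrt(6) / 3))

test_that("Vietoris-Rips uses the diameter convention", {
  fc <- build_vietoris_rips(unit_square)
  edges <- fc$values[fc$dims == 1]
  expect_equal(sort(edges), c(1, 1, 1, 1, sqrt(2), sqrt(2)))
  expect_equal(fc$values[fc$dims == 2], rep(sqrt(2), 4))
  # triangle enters with its longest edge (equilateral side 2 + far apex)
  apex <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0), c(50, 50, 50))
  fc2 <- build_vietoris_rips(apex)
  grp <- rep(seq_along(fc2$dims), fc2$dims + 1)
  vlist <- split(fc2$verts, grp)
  idx <- which(vapply(vlist, function(v)
    length(v) == 3 && all(sort(v) == 1:3), logical(1)))
  expect_equal(fc2$values[idx], 2)
})

test_that("small and oversized clouds are rejected", {
  expect_error(build_vietoris_rips(unit_square[1:2, ]), "too small")
  expect_error(build_alpha_complex(unit_square[1:3, ]), "too small")
  big <- random_cloud(151)
  expect_error(build_vietoris_rips(big), "alpha")
})

test_that("alpha complex of a regular tetrahedron has the exact values", {
  fc <- build_alpha_complex(regular_tetrahedron, jitter_amount = 0)
  expect_equal(sort(fc$values[fc$dims == 1]), rep(0.25, 6), tolerance = 1e-12)
  expect_equal(sort(fc$values[fc$dims == 2]), rep(1 / 3, 4), tolerance = 1e-12)
  expect_equal(fc$values[fc$dims == 3], 3 / 8, tolerance = 1e-12)
  bars <- compute_persistence(fc, dims = 1:2)
  expect_equal(iv(bars$H1), cbind(birth = rep(0.25, 3),
                                  death = rep(1 / 3, 3)),
               tolerance = 1e-12)
  expect_equal(iv(bars$H2), cbind(birth = 1 / 3, death = 3 / 8),
               tolerance = 1e-12)
})

test_that("square VR filtration yields the hand-reduced barcode", {
  bars <- compute_persistence(build_vietoris_rips(unit_square), dims = 1:2)
  expect_equal(iv(bars$H1), cbind(birth = 1, death = sqrt(2)),
               tolerance = 1e-12)
  expect_equal(nrow(bars$H2), 0)
})

test_that("persistence is deterministic and rejects invalid filtrations", {
  pc <- with_seed(3, random_cloud(15))
  fc <- build_vietoris_rips(pc)
  b1 <- compute_persistence(fc)
  b2 <- compute_persistence(fc)
  expect_identical(b1, b2)
  bad <- fc
  bad$values[bad$dims == 1][1] <- -1 # edge before its vertices
  expect_error(compute_persistence(bad), "filtration property")
})

test_that("VR thresholds below the diameter cap unpaired classes", {
  # square at threshold 1.2 < sqrt(2): the 4-cycle is born at 1 but its
  # filling triangles never enter, so the class is capped at the threshold
  fc <- build_vietoris_rips(unit_square, threshold = 1.2)
  expect_warning(bars <- compute_persistence(fc, dims = 1), "capping")
  expect_equal(iv(bars$H1), cbind(birth = 1, death = 1.2))
})

test_that("alpha barcodes in dims 1-2 are finite and Euler counts close", {
  with_seed(11, {
    for (rep in 1:5) {
      pc <- random_cloud(sample(10:25, 1))
      fc <- build_alpha_complex(pc)
      bars <- compute_persistence(fc, dims = 0:2)
      expect_true(all(is.finite(bars$H1)))
      expect_true(all(is.finite(bars$H2)))
      # Euler characteristic of the final complex (simplex counts) equals
      # the alternating sum of final Betti numbers, i.e. of essential
      # classes (the full alpha complex is contractible, so both are 1)
      chi_simplices <- sum((-1)^fc$dims)
      ess <- vapply(paste0("H", 0:2), function(h)
        sum(!is.finite(bars[[h]][, 2])), numeric(1))
      expect_equal(chi_simplices, sum((-1)^(0:2) * ess))
      expect_equal(chi_simplices, 1)
    }
  })
})

test_that("duplicate points are resolved by deterministic jitter", {
  pc <- rbind(random_cloud(8), random_cloud(8)[1, , drop = FALSE])
  fc1 <- build_alpha_complex(pc)
  fc2 <- build_alpha_complex(pc)
  expect_identical(compute_persistence(fc1), compute_persistence(fc2))
})

test_that("filtration and barcode serialization round out", {
  fc <- build_vietoris_rips(unit_square)
  path <- tempfile()
  write_filtration(fc, path)
  lines <- readLines(path)
  expect_length(lines, length(fc$dims))
  expect_match(lines[1], ": 0$|: 0\\.")
  bars <- compute_persistence(fc, dims = 1:2)
  csv <- tempfile(fileext = ".csv")
  write_barcodes(bars, csv)
  back <- read.csv(csv)
  expect_equal(back$k, 1)
  expect_equal(back$birth, 1)
  expect_equal(back$death, sqrt(2), tolerance = 1e-12)
})
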