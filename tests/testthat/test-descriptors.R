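bc <- function(...) barcode(rbind(...), 1)
empty_bc <- barcode(matrix(0, 0, 2), 1)

test_that("bottleneck distance matches the hand-derived examples", {
  P <- bc(c(0, 4))
  expect_equal(bottleneck_distance(P, P), 0)
  expect_equal(bottleneck_distance(bc(c(0, 2)), empty_bc), 1)
  expect_equal(bottleneck_distance(bc(c(0, 4)), bc(c(1, 5))), 1)
  expect_error(bottleneck_distance(barcode(rbind(c(0, 1)), 1),
                                   barcode(rbind(c(0, 1)), 2)),
               "different homological dimensions")
})

test_that("Wasserstein distance matches the hand-derived examples", {
  P <- bc(c(0, 4))
  expect_equal(wasserstein_distance(P, P), 0)
  expect_equal(wasserstein_distance(bc(c(0, 2)), empty_bc), sqrt(2))
  expect_equal(wasserstein_distance(bc(c(0, 4)), bc(c(1, 5))), sqrt(2))
  # literal (no outer root) form
  expect_equal(wasserstein_distance(bc(c(0, 4)), bc(c(1, 5)), root = FALSE), 2)
  expect_error(wasserstein_distance(P, P, q = 1), "supported")
})

test_that("matching distances agree with exhaustive enumeration", {
  with_seed(21, {
    for (rep in 1:25) {
      P <- random_barcode(); Q <- random_barcode()
      expect_equal(bottleneck_distance(P, Q),
                   brute_force_matching(P, Q, "bottleneck"),
                   tolerance = 1e-9)
      expect_equal(wasserstein_distance(P, Q),
                   brute_force_matching(P, Q, "wasserstein"),
                   tolerance = 1e-9)
    }
  })
})

test_that("metric axioms hold and bottleneck bounds Wasserstein", {
  with_seed(22, {
    for (rep in 1:10) {
      P <- random_barcode(); Q <- random_barcode(); R <- random_barcode()
      for (d in list(bottleneck_distance,
                     function(a, b) wasserstein_distance(a, b),
                     function(a, b) landscape_distance(build_landscape(a),
                                                       build_landscape(b)))) {
        expect_equal(d(P, P), 0, tolerance = 1e-12)
        expect_equal(d(P, Q), d(Q, P), tolerance = 1e-12)
        expect_lte(d(P, R), d(P, Q) + d(Q, R) + 1e-9)
        expect_gte(d(P, Q), 0)
      }
      expect_lte(bottleneck_distance(P, Q),
                 wasserstein_distance(P, Q) + 1e-9)
    }
  })
})

test_that("landscapes realise the tent closed forms", {
  L <- build_landscape(bc(c(0, 2)))
  expect_equal(landscape_value(L, 1, 1), 1)
  expect_equal(landscape_value(L, c(0, 2), 1), c(0, 0))
  expect_equal(landscape_value(L, 0.5, 1), 0.5)
  expect_equal(landscape_value(L, 1, 2), 0) # level 2 identically zero
  Lz <- build_landscape(empty_bc)
  expect_equal(nrow(Lz$lambda), 0)
  Ld <- build_landscape(bc(c(0, 2), c(0, 2)))
  expect_equal(landscape_value(Ld, 1, 1), landscape_value(Ld, 1, 2))
})

test_that("landscape L2 distance matches analytic values", {
  A <- build_landscape(bc(c(0, 2)))
  B <- build_landscape(empty_bc)
  expect_equal(landscape_distance(A, A), 0)
  expect_equal(landscape_distance(A, B), sqrt(2 / 3), tolerance = 1e-12)
  C2 <- build_landscape(bc(c(0, 2), c(0, 2)))
  expect_equal(landscape_distance(A, C2), sqrt(2 / 3), tolerance = 1e-12)
})

test_that("landscape levels are ordered, Lipschitz, and stable", {
  with_seed(23, {
    for (rep in 1:10) {
      P <- random_barcode(6)
      if (nrow(P) == 0) next
      L <- build_landscape(P)
      grid <- seq(min(L$t), max(L$t), length.out = 200)
      vals <- vapply(seq_len(nrow(L$lambda)),
                     function(l) landscape_value(L, grid, l),
                     numeric(length(grid)))
      if (ncol(vals) > 1) {
        expect_true(all(diff(t(vals)) <= 1e-12)) # lambda_1 >= lambda_2 >= ...
      }
      expect_true(all(vals >= -1e-12))
      slopes <- abs(diff(vals[, 1])) / diff(grid)
      expect_true(all(slopes <= 1 + 1e-9)) # 1-Lipschitz
      # continuity under endpoint perturbation
      eps <- 1e-3
      Pp <- barcode(unclass(P) + matrix(runif(length(P), -eps, eps),
                                        ncol = 2), 1)
      d_small <- landscape_distance(L, build_landscape(Pp))
      expect_lt(d_small, 10 * eps * sqrt(nrow(P) * diff(range(L$t)) + 1))
    }
  })
})

test_that("normalization divides by the mean point count", {
  expect_equal(normalize_distance(10, 100, 200), 10 / 150)
  expect_equal(normalize_distance(0, 5, 9), 0)
  expect_equal(normalize_distance(7, 50, 50), 7 / 50)
  expect_error(normalize_distance(1, 0, 10), "positive")
})
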