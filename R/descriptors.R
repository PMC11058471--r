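check_same_dim <- function(P, Q) {
  kP <- attr(P, "k"); kQ <- attr(Q, "k")
  if (!is.null(kP) && !is.null(kQ) && kP != kQ)
    stop("barcodes are in different homological dimensions (",
         kP, " vs ", kQ, ")")
}

as_intervals <- function(P) {
  m <- unclass(P)
  matrix(as.numeric(m), ncol = 2)
}

#' Bottleneck distance between two barcodes
#'
#' The infimum over augmented matchings of the largest L-infinity distance
#' between matched intervals, where unmatched intervals are matched to their
#' nearest diagonal point (cost = persistence / 2). Computed exactly by
#' binary search over the candidate cost set with bipartite
#' perfect-matching feasibility tests.
#'
#' @param P,Q `barcode` objects (or two-column birth/death matrices) in the
#'   same homological dimension.
#' @return Non-negative distance, in the units of the filtration.
#' @export
bottleneck_distance <- function(P, Q) {
  check_same_dim(P, Q)
  bottleneck_cpp(as_intervals(P), as_intervals(Q))
}

#' Wasserstein distance between two barcodes
#'
#' Minimum over augmented bijections (diagonal projections allowed;
#' diagonal-to-diagonal pairs cost nothing) of the sum of squared Euclidean
#' distances between matched intervals, computed exactly by optimal
#' assignment on the augmented cost matrix. With `root = TRUE` (default)
#' the square root of the minimal sum is returned, which is the metric
#' W_2; `root = FALSE` returns the raw minimal sum of squares.
#'
#' @param P,Q `barcode` objects in the same homological dimension.
#' @param q Outer exponent; only 2 is supported.
#' @param internal_p Ground metric exponent; only 2 is supported.
#' @param root Apply the outer q-th root (default `TRUE`).
#' @return Non-negative distance.
#' @export
wasserstein_distance <- function(P, Q, q = 2, internal_p = 2, root = TRUE) {
  if (q != 2 || internal_p != 2)
    stop("only q = 2 with internal_p = 2 is supported")
  check_same_dim(P, Q)
  Pi <- as_intervals(P); Qi <- as_intervals(Q)
  m <- nrow(Pi); n <- nrow(Qi)
  if (m == 0 && n == 0) return(0)
  N <- m + n
  cost <- matrix(0, N, N)
  if (m > 0 && n > 0) {
    cost[1:m, 1:n] <- outer(Pi[, 1], Qi[, 1], "-")^2 +
      outer(Pi[, 2], Qi[, 2], "-")^2
  }
  dP <- (Pi[, 2] - Pi[, 1])^2 / 2 # squared L2 distance to the diagonal
  dQ <- (Qi[, 2] - Qi[, 1])^2 / 2
  if (m > 0) cost[1:m, (n + 1):N] <- matrix(dP, m, m)
  if (n > 0) cost[(m + 1):N, 1:n] <- matrix(dQ, n, n, byrow = TRUE)
  total <- assignment_cost_cpp(cost)
  if (root) sqrt(total) else total
}

#' Build the persistence landscape of a barcode
#'
#' The l-th landscape level at t is the l-th largest value of the tent
#' functions `max(0, min(t - b, d - t))` over the intervals (b, d). The
#' landscape is represented exactly by its breakpoints: between consecutive
#' breakpoints every level is linear, so no grid error is introduced.
#'
#' @param P A `barcode`.
#' @param max_levels Number of levels to keep; default all (= number of
#'   intervals).
#' @return A `persistence_landscape`: list with `k`, breakpoints `t`, and a
#'   levels x length(t) matrix `lambda` of level values.
#' @export
build_landscape <- function(P, max_levels = NULL) {
  k <- attr(P, "k") %||% NA_integer_
  iv <- as_intervals(P)
  m <- nrow(iv)
  if (m == 0) {
    return(structure(list(k = k, t = c(0, 1),
                          lambda = matrix(0, 0, 2)),
                     class = "persistence_landscape"))
  }
  b <- iv[, 1]; d <- iv[, 2]
  # breakpoints: endpoints and all pairwise tent-line crossings (b_i + d_j)/2
  grid <- sort(unique(c(b, d, as.vector(outer(b, d, "+")) / 2)))
  tent <- function(t) {
    v <- vapply(seq_len(m),
                function(i) pmax(0, pmin(t - b[i], d[i] - t)),
                numeric(length(t)))
    if (length(t) == 1) v <- matrix(v, nrow = 1)
    v
  }
  vals <- tent(grid) # |grid| x m
  # row-wise descending sort with a single radix order() pass
  lam <- matrix(vals[order(row(vals), -vals)], nrow = nrow(vals), byrow = TRUE)
  nlev <- min(max_levels %||% m, m)
  structure(list(k = k, t = grid,
                 lambda = t(lam[, seq_len(nlev), drop = FALSE])),
            class = "persistence_landscape")
}

#' @export
print.persistence_landscape <- function(x, ...) {
  cat("<persistence_landscape> k =", x$k, "-", nrow(x$lambda),
      "levels over [", min(x$t), ",", max(x$t), "]\n")
  invisible(x)
}

#' Evaluate landscape levels at given points
#'
#' @param L A `persistence_landscape`.
#' @param t Numeric vector of evaluation points.
#' @param level Level index (1 = top level).
#' @return Values of the requested level at `t` (0 outside the support and
#'   for levels beyond the stored ones).
#' @export
landscape_value <- function(L, t, level = 1) {
  if (level > nrow(L$lambda)) return(rep(0, length(t)))
  stats::approx(L$t, L$lambda[level, ], xout = t, yleft = 0, yright = 0,
                rule = 2, ties = "ordered")$y
}

#' L2 distance between two persistence landscapes
#'
#' The square root of the summed squared L2 differences of the level
#' functions, computed exactly by piecewise-quadratic integration over the
#' merged breakpoint grid (the difference of two piecewise-linear functions
#' is piecewise linear there, so its square integrates in closed form).
#'
#' @param A,B `persistence_landscape` objects in the same homological
#'   dimension.
#' @param p Norm exponent; only 2 is supported.
#' @return Non-negative distance.
#' @export
landscape_distance <- function(A, B, p = 2) {
  if (p != 2) stop("only p = 2 is supported")
  if (!is.na(A$k) && !is.na(B$k) && A$k != B$k)
    stop("landscapes are in different homological dimensions")
  grid <- sort(unique(c(A$t, B$t)))
  nlev <- max(nrow(A$lambda), nrow(B$lambda))
  if (nlev == 0) return(0)
  # evaluate all levels on the merged grid with one interpolation pass
  eval_all <- function(L) {
    out <- matrix(0, nlev, length(grid))
    if (nrow(L$lambda) == 0) return(out)
    idx <- findInterval(grid, L$t, all.inside = TRUE)
    t1 <- L$t[idx]; t2 <- L$t[idx + 1]
    w <- ifelse(t2 > t1, (grid - t1) / (t2 - t1), 0)
    inside <- grid >= L$t[1] & grid <= L$t[length(L$t)]
    lev <- seq_len(nrow(L$lambda))
    Y <- L$lambda[lev, idx, drop = FALSE] *
      rep(1 - w, each = length(lev)) +
      L$lambda[lev, idx + 1, drop = FALSE] * rep(w, each = length(lev))
    Y[, !inside] <- 0
    out[lev, ] <- Y
    out
  }
  dy <- eval_all(A) - eval_all(B)
  y1 <- dy[, -ncol(dy), drop = FALSE]
  y2 <- dy[, -1, drop = FALSE]
  seg <- y1 * y1 + y1 * y2 + y2 * y2
  total <- sum(rep(diff(grid), each = nlev) * seg) / 3
  sqrt(total)
}

#' Normalize a PH-distance by average point count
#'
#' Divides a raw barcode or landscape distance by the average number of
#' points of the two compared clouds, counting only points actually used
#' (after any masking). This removes the strong dependence of raw
#' PH-distances on protein length.
#'
#' @param d Raw distance.
#' @param nA,nB Point counts of the two clouds.
#' @return `d / ((nA + nB) / 2)`.
#' @export
normalize_distance <- function(d, nA, nB) {
  if (nA <= 0 || nB <= 0) stop("point counts must be positive")
  d / ((nA + nB) / 2)
}
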