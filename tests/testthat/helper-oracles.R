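# Independent oracles and fixture builders shared across tests.

# Exhaustive search over augmented matchings between two barcodes:
# every interval of P is matched to an unused interval of Q or to the
# diagonal, leftover Q intervals go to the diagonal. Exact for small inputs.
brute_force_matching <- function(P, Q, type = c("bottleneck", "wasserstein")) {
  type <- match.arg(type)
  P <- matrix(as.numeric(P), ncol = 2)
  Q <- matrix(as.numeric(Q), ncol = 2)
  m <- nrow(P); n <- nrow(Q)
  diagP <- if (type == "bottleneck") (P[, 2] - P[, 1]) / 2
           else (P[, 2] - P[, 1])^2 / 2
  diagQ <- if (type == "bottleneck") (Q[, 2] - Q[, 1]) / 2
           else (Q[, 2] - Q[, 1])^2 / 2
  pair_cost <- function(i, j) {
    if (type == "bottleneck")
      max(abs(P[i, 1] - Q[j, 1]), abs(P[i, 2] - Q[j, 2]))
    else (P[i, 1] - Q[j, 1])^2 + (P[i, 2] - Q[j, 2])^2
  }
  comb <- if (type == "bottleneck") max else sum
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > m) {
      rest <- diagQ[seq_len(n)][!used[seq_len(n)]]
      total <- if (length(rest) > 0) comb(acc, comb(rest)) else acc
      if (total < best) best <<- total
      return()
    }
    for (j in seq_len(n)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1, used, comb(acc, pair_cost(i, j)))
        used[j] <- FALSE
      }
    }
    rec(i + 1, used, comb(acc, diagP[i]))
  }
  rec(1, rep(FALSE, max(n, 1)), if (type == "bottleneck") 0 else 0)
  if (m == 0 && n == 0) best <- 0
  if (type == "wasserstein") sqrt(best) else best
}

random_barcode <- function(max_intervals = 6, k = 1) {
  m <- sample(0:max_intervals, 1)
  if (m == 0) return(barcode(matrix(0, 0, 2), k))
  b <- runif(m, 0, 5)
  d <- b + runif(m, 0.05, 4)
  barcode(cbind(b, d), k)
}

random_cloud <- function(n, scale = 10) {
  matrix(runif(3 * n, 0, scale), ncol = 3)
}

# Run the independent Python persistence oracle on a point matrix.
# Returns a data.frame (dim, birth, death) sorted like sort_bars().
run_py_oracle <- function(points, mode, threshold = "auto") {
  script <- test_path("oracle_persistence.py")
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)))
  write.table(points, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  status <- system2("python", c(script, fin, mode, threshold, fout),
                    stdout = NULL, stderr = NULL)
  stopifnot(status == 0)
  out <- read.csv(fout)
  out$death[out$death == Inf] <- Inf
  sort_bars(out)
}

# Strip class/attributes from a barcode for plain-matrix comparison.
iv <- function(b) {
  m <- matrix(as.numeric(b), ncol = 2)
  colnames(m) <- c("birth", "death")
  m
}

sort_bars <- function(df) {
  df <- df[order(df$dim, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Flatten compute_persistence() output (named list of barcodes) to the
# oracle's data.frame layout.
bars_to_df <- function(bars) {
  rows <- do.call(rbind, lapply(bars, function(b) {
    k <- attr(b, "k")
    if (nrow(b) == 0)
      return(data.frame(dim = integer(), birth = numeric(),
                        death = numeric()))
    data.frame(dim = k, birth = b[, 1], death = b[, 2])
  }))
  sort_bars(rows)
}

expect_same_bars <- function(mine, oracle, tol = 1e-9) {
  expect_equal(nrow(mine), nrow(oracle))
  expect_equal(mine$dim, oracle$dim)
  expect_true(all(abs(mine$birth - oracle$birth) < tol))
  fin <- is.finite(oracle$death)
  expect_equal(is.finite(mine$death), fin)
  expect_true(all(abs(mine$death[fin] - oracle$death[fin]) < tol))
}

# Minimal PDB writer for handcrafted structure fixtures.
make_pdb_text <- function(atoms) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$type, i, a$name, "", a$resid, "A", a$resno, "",
            a$x, a$y, a$z, 1.00, a$b, a$elem)
  }, character(1))
  paste(c(lines, "END"), collapse = "\n")
}

two_residue_pdb <- function(b1 = 95, b2 = 60) {
  atoms <- data.frame(
    type = "ATOM",
    name = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O"),
    resid = c(rep("ALA", 5), rep("GLY", 4)),
    resno = c(rep(1L, 5), rep(2L, 4)),
    x = c(0, 1.4, 2.4, 3.0, 1.6, 3.1, 4.5, 5.5, 6.1),
    y = c(0, 0.2, 1.1, 0.8, -1.2, 2.2, 2.4, 3.3, 3.0),
    z = c(0, 0.1, 0.3, 1.2, 0.6, 0.2, 0.4, 0.6, 1.5),
    b = c(rep(b1, 5), rep(b2, 4)),
    elem = c("N", "C", "C", "O", "C", "N", "C", "C", "O"),
    stringsAsFactors = FALSE)
  make_pdb_text(atoms)
}

# Small alignment fixture used across evodist tests.
toy_alignment <- function(rows) {
  read_alignment(paste(paste0(">", names(rows), "\n", unname(rows)),
                       collapse = "\n"))
}
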