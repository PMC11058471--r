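#' Build a Vietoris-Rips filtration from a point cloud
#'
#' Every simplex up to `max_dim` whose vertex set has diameter (maximum
#' pairwise Euclidean distance) at most `threshold` is included, with the
#' diameter as its filtration value. The default threshold is the cloud
#' diameter, which guarantees that every positive-dimensional class dies;
#' `max_dim = 3` makes homology in dimension 2 computable.
#'
#' @param pc A `point_cloud`, or a plain n x 3 matrix.
#' @param max_dim Maximum simplex dimension (default 3).
#' @param threshold Filtration threshold; `NULL` means the cloud diameter.
#' @param cap Maximum allowed number of points (default 150); the number of
#'   simplices grows as n^4, so larger clouds should use the alpha complex.
#' @return A `filtered_complex` (kind `"VR"`, values in Angstrom).
#' @export
build_vietoris_rips <- function(pc, max_dim = 3, threshold = NULL, cap = 150) {
  pts <- cloud_points(pc)
  n <- nrow(pts)
  if (n < 4) stop("cloud too small for 3D filtration")
  if (n > cap)
    stop("cloud has ", n, " points (cap ", cap,
         "): the Vietoris-Rips complex would be enormous; ",
         "use build_alpha_complex() instead")
  diam <- max(stats::dist(pts))
  thr <- threshold %||% diam
  fc <- vr_complex_cpp(pts, as.integer(max_dim), thr)
  structure(list(kind = "VR", n_points = n, dims = fc$dims,
                 values = fc$values, verts = fc$verts,
                 threshold = thr, full = thr >= diam),
            class = "filtered_complex")
}

#' Build an alpha-complex filtration from a point cloud
#'
#' Simplices are those of the 3D Delaunay triangulation; the filtration
#' value of a simplex is the squared radius of its smallest empty
#' circumscribing ball (Gabriel simplices get their squared circumradius,
#' other faces inherit the minimum value of their cofaces). A deterministic
#' jitter puts the points in general position; if the triangulation fails
#' the empty-circumsphere verification the jitter is enlarged and the
#' construction retried.
#'
#' @param pc A `point_cloud`, or a plain n x 3 matrix.
#' @param jitter_amount Initial jitter magnitude in Angstrom.
#' @param jitter_seed Seed of the deterministic jitter.
#' @param max_retries Retries with 10x jitter on degeneracy.
#' @return A `filtered_complex` (kind `"AC"`, values in squared Angstrom).
#' @export
build_alpha_complex <- function(pc, jitter_amount = 1e-6, jitter_seed = 1L,
                                max_retries = 3) {
  pts <- cloud_points(pc)
  n <- nrow(pts)
  if (n < 4) stop("cloud too small for 3D filtration")
  # center (conditioning) and insert in shuffled order (chain order is
  # adversarial for incremental Delaunay); neither affects alpha values
  pts <- sweep(pts, 2, colMeans(pts))
  perm <- with_seed(jitter_seed, sample.int(n))
  inv <- order(perm)
  amount <- jitter_amount
  for (try in seq_len(max_retries + 1)) {
    jp <- jitter_points(pts, amount, jitter_seed + try - 1L)[perm, ,
                                                             drop = FALSE]
    del <- delaunay_cpp(jp)
    if (isTRUE(del$ok)) {
      fc <- alpha_values_cpp(jp, del$tetra)
      # restore original vertex numbering (row j of jp is point perm[j])
      verts <- perm[fc$verts]
      return(structure(list(kind = "AC", n_points = n, dims = fc$dims,
                            values = fc$values, verts = verts,
                            threshold = Inf, full = TRUE,
                            points = jp[inv, , drop = FALSE]),
                       class = "filtered_complex"))
    }
    amount <- amount * 10
  }
  stop("degenerate point configuration: Delaunay triangulation failed ",
       "after ", max_retries, " jitter retries")
}

cloud_points <- function(pc) {
  if (inherits(pc, "point_cloud")) {
    pts <- pc$points
  } else {
    pts <- as.matrix(pc)
  }
  stopifnot(is.numeric(pts), ncol(pts) == 3, all(is.finite(pts)))
  unname(pts)
}

#' @export
print.filtered_complex <- function(x, ...) {
  cat("<filtered_complex>", x$kind, "-", x$n_points, "points,",
      length(x$dims), "simplices\n")
  invisible(x)
}

#' Construct a barcode object
#'
#' @param intervals Two-column matrix of (birth, death) with death > birth.
#' @param k Homological dimension.
#' @return A `barcode`: the interval matrix with a dimension attribute.
#' @export
barcode <- function(intervals, k) {
  m <- matrix(as.numeric(intervals), ncol = 2,
              dimnames = list(NULL, c("birth", "death")))
  if (nrow(m) > 0 && any(m[, 2] <= m[, 1]))
    stop("barcode intervals must satisfy death > birth")
  structure(m, k = as.integer(k), class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat("<barcode> k =", attr(x, "k"), "-", nrow(x), "intervals\n")
  if (nrow(x) > 0) print(unclass(x)[seq_len(min(nrow(x), 10)), , drop = FALSE])
  invisible(x)
}

#' Compute persistence barcodes of a filtered complex
#'
#' Runs the standard persistence algorithm: simplices ordered by
#' (filtration value, dimension, lexicographic vertex tuple), boundary
#' matrix reduced left-to-right over the field with two elements.
#' Zero-persistence pairs are discarded. For a Vietoris-Rips filtration
#' truncated below the cloud diameter, unpaired positive-dimensional
#' classes are capped at the threshold (with a warning). Dimension-0
#' descriptors are not part of the pipeline output but can be requested
#' for diagnostics.
#'
#' @param fc A `filtered_complex`.
#' @param dims Homological dimensions to report (default `1:2`).
#' @return Named list (`H1`, `H2`, optionally `H0`) of `barcode` objects.
#' @export
compute_persistence <- function(fc, dims = 1:2) {
  stopifnot(inherits(fc, "filtered_complex"))
  pm <- persistence_cpp(fc$dims, fc$values, fc$verts)
  out <- list()
  for (k in sort(dims)) {
    rows <- pm[pm[, 1] == k, , drop = FALSE]
    inf_rows <- is.infinite(rows[, 3])
    if (k >= 1 && any(inf_rows)) {
      if (isTRUE(fc$full))
        stop("unexpected essential class in dimension ", k,
             " of a fully resolved filtration")
      warning("capping ", sum(inf_rows), " unpaired dimension-", k,
              " class(es) at the filtration threshold")
      rows[inf_rows, 3] <- fc$threshold
      rows <- rows[rows[, 3] > rows[, 2], , drop = FALSE]
    }
    out[[paste0("H", k)]] <- barcode(rows[, 2:3, drop = FALSE], k)
  }
  out
}

#' Write a filtered complex as plain text
#'
#' One simplex per line, `"v1 v2 ... : value"`, in filtration order.
#'
#' @param fc A `filtered_complex`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_filtration <- function(fc, path) {
  stopifnot(inherits(fc, "filtered_complex"))
  idx <- order(fc$values, fc$dims)
  off <- c(0, cumsum(fc$dims + 1))
  lines <- vapply(idx, function(i) {
    v <- fc$verts[(off[i] + 1):off[i + 1]]
    paste(paste(sort(v), collapse = " "), ":", format(fc$values[i], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write barcodes to CSV
#'
#' @param barcodes Named list of `barcode` objects (as returned by
#'   [compute_persistence()]).
#' @param path Output file (columns `k`, `birth`, `death`).
#' @return `path`, invisibly.
#' @export
write_barcodes <- function(barcodes, path) {
  rows <- do.call(rbind, lapply(barcodes, function(b) {
    if (nrow(b) == 0) return(NULL)
    data.frame(k = attr(b, "k"), birth = b[, 1], death = b[, 2])
  }))
  if (is.null(rows)) rows <- data.frame(k = integer(), birth = numeric(),
                                        death = numeric())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
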