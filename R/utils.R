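#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers do not disturb the global random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Deterministic jitter for point clouds
#'
#' Adds a uniform perturbation of magnitude `amount` to every coordinate,
#' drawn under a fixed seed. Used to put synthetic coordinates in general
#' position before Delaunay triangulation; the default 1e-6 Angstrom is far
#' below atomic coordinate precision.
#'
#' @param points Numeric matrix (n x 3).
#' @param amount Maximum absolute perturbation per coordinate (Angstrom).
#' @param seed Integer seed for the perturbation.
#' @return Perturbed matrix of the same shape.
#' @export
jitter_points <- function(points, amount = 1e-6, seed = 1L) {
  stopifnot(is.matrix(points), ncol(points) == 3)
  with_seed(seed, points + matrix(stats::runif(length(points), -amount, amount),
                                  nrow = nrow(points)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
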