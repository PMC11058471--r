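#' Read a multiple protein alignment from aligned FASTA
#'
#' @param fasta Path to an aligned FASTA file, or FASTA-format text.
#' @return A `protein_alignment`: list with `ids`, `rows` (named character
#'   vector of equal-length aligned strings, uppercased) and `ncol`.
#' @export
read_alignment <- function(fasta) {
  if (length(fasta) == 1 && !grepl("\n", fasta) && file.exists(fasta)) {
    path <- fasta
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(paste(fasta, collapse = "\n"), "\n")), path)
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2) stop("alignment needs at least 2 sequences")
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  rows <- toupper(as.character(ss))
  names(rows) <- ids
  w <- unique(nchar(rows))
  if (length(w) != 1)
    stop("ragged alignment: rows have differing lengths (",
         paste(w, collapse = ", "), ")")
  structure(list(ids = ids, rows = rows, ncol = w),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("<protein_alignment>", length(x$ids), "sequences x", x$ncol,
      "columns\n")
  invisible(x)
}

align_chars <- function(m, id) {
  if (!id %in% m$ids) stop("sequence '", id, "' not in alignment")
  strsplit(m$rows[[id]], "")[[1]]
}

#' Observed p-distance between two aligned sequences
#'
#' Proportion of differing sites among alignment columns where neither row
#' has a gap (pairwise deletion). Computed from the untrimmed alignment.
#'
#' @param m A `protein_alignment`.
#' @param idA,idB Sequence identifiers.
#' @return Value in `[0, 1]`.
#' @export
p_distance <- function(m, idA, idB) {
  a <- align_chars(m, idA)
  b <- align_chars(m, idB)
  comparable <- a != "-" & b != "-"
  if (!any(comparable)) stop("no overlapping sites between '", idA,
                             "' and '", idB, "'")
  mean(a[comparable] != b[comparable])
}

#' Per-pair indel map from a multiple alignment
#'
#' Records the alignment columns where exactly one of the two rows has a
#' gap, and the ungapped residue indices of the opposing residues, which
#' are the residues to mask from each structure before computing
#' PH-distances for this pair. Columns gapped in both rows carry no
#' information for the pair and are ignored.
#'
#' @param m A `protein_alignment`.
#' @param idA,idB Sequence identifiers.
#' @return A `pair_indel_map`: list with `idA`, `idB`, `columns_gapped`,
#'   `residues_to_mask_A`, `residues_to_mask_B` and `gap_count`.
#' @export
pair_indel_map <- function(m, idA, idB) {
  a <- align_chars(m, idA)
  b <- align_chars(m, idB)
  gapA <- a == "-"
  gapB <- b == "-"
  one_gap <- xor(gapA, gapB)
  resA <- cumsum(!gapA) # residue index of column in sequence A
  resB <- cumsum(!gapB)
  structure(list(
    idA = idA, idB = idB,
    columns_gapped = which(one_gap),
    residues_to_mask_A = resA[one_gap & gapB],
    residues_to_mask_B = resB[one_gap & gapA],
    gap_count = sum(one_gap)
  ), class = "pair_indel_map")
}

#' Read a phylogenetic tree with branch lengths from Newick
#'
#' @param newick Path to a Newick file, or Newick text.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(newick) {
  tr <- tryCatch({
    if (length(newick) == 1 && !grepl("[(;]", newick) &&
        file.exists(newick)) {
      ape::read.tree(newick)
    } else {
      ape::read.tree(text = paste(newick, collapse = "\n"))
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick text")
  if (length(tr$tip.label) < 2) stop("fewer than 2 leaves")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("branch lengths required for patristic distances")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j (the ML-distance when the tree is a maximum-likelihood
#' tree, in expected substitutions per site).
#'
#' @param t A `phylo` object with branch lengths.
#' @return Symmetric matrix with zero diagonal, rows/columns named by the
#'   tip labels.
#' @export
patristic_matrix <- function(t) {
  stopifnot(inherits(t, "phylo"))
  if (is.null(t$edge.length)) stop("branch lengths required")
  d <- ape::cophenetic.phylo(t)
  d[t$tip.label, t$tip.label]
}
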