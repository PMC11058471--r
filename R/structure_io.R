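#' Parse a protein structure from PDB text or file
#'
#' Reads `ATOM` records of a single chain from a PDB file (the format
#' AlphaFold2 writes, with the per-residue confidence index, pLDDT, stored in
#' the B-factor column). Waters, `HETATM` records, hydrogens and non-primary
#' alternate locations are skipped. The confidence of every atom in a residue
#' is taken from the B-factor of that residue's CA atom, which makes the rule
#' well-defined for experimental files too. Residues lacking a CA atom are
#' dropped with a warning.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param id Identifier for the structure; defaults to the file name or
#'   `"structure"` for literal text.
#' @param chain Chain identifier to read; default the first chain present.
#' @return A `protein_structure`: list with `id`, `atoms` (data.frame with
#'   `residue_index`, `residue_name`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `confidence`) and `sequence` (1-letter string).
#' @export
read_structure <- function(pdb, id = NULL, chain = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    id <- id %||% sub("\\.pdb$", "", basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
    id <- id %||% "structure"
  }
  pb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                                  verbose = FALSE)),
                 error = function(e) stop("no atoms: ", conditionMessage(e)))
  at <- pb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms")
  chain <- chain %||% at$chain[1]
  at <- at[is.na(at$chain) | at$chain == chain, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9 ]", "", at$elety[bad]), 1, 1)
  keep <- toupper(elem) != "H" & at$resid != "HOH"
  at <- at[keep, , drop = FALSE]
  elem <- toupper(elem[keep])
  if (nrow(at) == 0) stop("no atoms")

  # per-residue confidence from the CA B-factor
  is_ca <- at$elety == "CA"
  res_with_ca <- unique(at$resno[is_ca])
  dropped <- setdiff(unique(at$resno), res_with_ca)
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " residue(s) without a CA atom")
    at <- at[at$resno %in% res_with_ca, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no atoms")
  elem <- toupper(at$elesy)
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[0-9 ]", "", at$elety[bad]), 1, 1)
  is_ca <- at$elety == "CA"
  conf_of <- at$b[is_ca]
  names(conf_of) <- as.character(at$resno[is_ca])

  atoms <- data.frame(
    residue_index = at$resno,
    residue_name = at$resid,
    atom_name = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    confidence = unname(conf_of[as.character(at$resno)]),
    stringsAsFactors = FALSE
  )
  seq1 <- bio3d::aa321(at$resid[is_ca])
  structure(list(id = id, atoms = atoms,
                 sequence = paste(seq1, collapse = "")),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure>", x$id, "-", nchar(x$sequence), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Extract an atom-selection point cloud from a structure
#'
#' Builds one of the five atom-selection point clouds used throughout the
#' pipeline: alpha carbons (`CA`), all heavy atoms (`ALL_ATOMS`), or all
#' carbon / nitrogen / oxygen atoms (`ALL_C`, `ALL_N`, `ALL_O`), including
#' backbone atoms of the element by default.
#'
#' @param s A `protein_structure`.
#' @param selector One of `"CA"`, `"ALL_ATOMS"`, `"ALL_C"`, `"ALL_N"`,
#'   `"ALL_O"`.
#' @param sidechain_only For the element selectors, exclude the backbone
#'   atoms of that element (CA and carbonyl C for carbon, amide N for
#'   nitrogen, carbonyl O and OXT for oxygen).
#' @return A `point_cloud`: list with `points` (n x 3 matrix, Angstrom),
#'   `residue_of_point`, `selector`, `n`, and the full residue index set of
#'   the source structure (used to validate masks).
#' @export
extract_point_cloud <- function(s, selector = c("CA", "ALL_ATOMS", "ALL_C",
                                                "ALL_N", "ALL_O"),
                                sidechain_only = FALSE) {
  selector <- match.arg(selector)
  stopifnot(inherits(s, "protein_structure"))
  at <- s$atoms
  if (nrow(at) == 0) stop("empty structure")
  keep <- switch(selector,
    CA = at$atom_name == "CA",
    ALL_ATOMS = rep(TRUE, nrow(at)),
    ALL_C = at$element == "C",
    ALL_N = at$element == "N",
    ALL_O = at$element == "O"
  )
  if (sidechain_only && selector %in% c("ALL_C", "ALL_N", "ALL_O")) {
    backbone <- switch(selector,
                       ALL_C = c("CA", "C"),
                       ALL_N = "N",
                       ALL_O = c("O", "OXT"))
    keep <- keep & !(at$atom_name %in% backbone)
  }
  at <- at[keep, , drop = FALSE]
  structure(list(points = unname(as.matrix(at[, c("x", "y", "z")])),
                 residue_of_point = at$residue_index,
                 selector = selector,
                 n = nrow(at),
                 source_residues = unique(s$atoms$residue_index),
                 structure_id = s$id),
            class = "point_cloud")
}

subset_cloud <- function(pc, keep) {
  pc$points <- pc$points[keep, , drop = FALSE]
  pc$residue_of_point <- pc$residue_of_point[keep]
  pc$n <- nrow(pc$points)
  pc
}

#' Mask low-confidence residues from a point cloud
#'
#' Removes all points belonging to residues whose confidence index falls
#' below the threshold. Whole residues are masked, for every selector.
#'
#' @param pc A `point_cloud`.
#' @param s The `protein_structure` the cloud came from.
#' @param threshold Confidence threshold in percent (default 70).
#' @param strict If `TRUE` retain only confidence strictly greater than the
#'   threshold; default retains `>=`.
#' @return A filtered `point_cloud`.
#' @export
mask_low_confidence <- function(pc, s, threshold = 70, strict = FALSE) {
  stopifnot(inherits(pc, "point_cloud"), inherits(s, "protein_structure"))
  conf <- s$atoms$confidence[match(pc$residue_of_point, s$atoms$residue_index)]
  if (anyNA(conf)) stop("cloud residues not resolvable against structure")
  keep <- if (strict) conf > threshold else conf >= threshold
  if (!any(keep)) stop("empty cloud after CI masking")
  subset_cloud(pc, keep)
}

#' Mask indel residues from a pair of point clouds
#'
#' For each alignment column where exactly one of the two sequences has a
#' gap, removes all points of the opposing residue from that protein's
#' cloud. Masking is pair-specific: the same structure keeps different
#' points depending on the partner it is compared with.
#'
#' @param pcA,pcB `point_cloud`s of the two proteins.
#' @param pair_map A `pair_indel_map` for the same two sequences (see
#'   [pair_indel_map()]).
#' @return List with elements `A` and `B`, the masked clouds.
#' @export
mask_indel_residues <- function(pcA, pcB, pair_map) {
  stopifnot(inherits(pair_map, "pair_indel_map"))
  mask1 <- function(pc, mask) {
    if (length(mask) == 0) return(pc)
    if (!all(mask %in% pc$source_residues))
      stop("indel mask refers to residues absent from the structure")
    keep <- !(pc$residue_of_point %in% mask)
    subset_cloud(pc, keep)
  }
  list(A = mask1(pcA, pair_map$residues_to_mask_A),
       B = mask1(pcB, pair_map$residues_to_mask_B))
}
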