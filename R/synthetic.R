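AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Configuration of a synthetic protein family
#'
#' Bundles the parameters of the coupled sequence-structure evolution
#' simulator. Defaults are chosen to emulate moderately divergent prokaryotic
#' protein families: around one expected substitution per site across the
#' tree, occasional short indels, and a small fraction of low-confidence
#' residues.
#'
#' @param n_taxa Number of homologs (>= 7; smaller families carry too little
#'   signal and are discarded in practice).
#' @param seq_length Root sequence length in residues (>= 30).
#' @param birth_rate Yule speciation rate; larger values give shallower
#'   trees (expected depth roughly `log(n_taxa) / birth_rate`).
#' @param sub_rate Expected substitutions per site per unit branch length.
#' @param indel_rate Expected indel events per sequence per unit branch
#'   length.
#' @param indel_len_mean Mean indel length (geometric, >= 1).
#' @param struct_noise_sd Brownian structural noise, Angstrom per coordinate
#'   per square root of unit branch length.
#' @param low_ci_fraction Fraction of residues flagged low-confidence.
#' @param seed Integer seed; all randomness of the family flows from it.
#' @return A `synthetic_family_config` list.
#' @export
synthetic_family_config <- function(n_taxa = 10, seq_length = 100,
                                    birth_rate = 2, sub_rate = 1,
                                    indel_rate = 0.3, indel_len_mean = 3,
                                    struct_noise_sd = 0.25,
                                    low_ci_fraction = 0.06, seed = 1L) {
  if (n_taxa < 7) stop("n_taxa must be >= 7")
  if (seq_length < 30) stop("seq_length must be >= 30")
  if (any(c(birth_rate, sub_rate, indel_rate, struct_noise_sd) < 0))
    stop("rates must be non-negative")
  if (indel_len_mean < 1) stop("indel_len_mean must be >= 1")
  if (low_ci_fraction < 0 || low_ci_fraction > 1)
    stop("low_ci_fraction must be in [0, 1]")
  structure(list(n_taxa = as.integer(n_taxa),
                 seq_length = as.integer(seq_length),
                 birth_rate = birth_rate, sub_rate = sub_rate,
                 indel_rate = indel_rate, indel_len_mean = indel_len_mean,
                 struct_noise_sd = struct_noise_sd,
                 low_ci_fraction = low_ci_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_family_config")
}

#' Simulate a Yule tree
#'
#' Pure-birth process started from two lineages: waiting times are
#' exponential with rate `birth_rate` times the number of live lineages,
#' the splitting lineage is uniform, and after the n-th tip appears all
#' tips are extended by a final exponential waiting time, giving an
#' ultrametric tree with exponential branch lengths.
#'
#' @param n_taxa Number of tips (>= 7).
#' @param birth_rate Speciation rate per lineage.
#' @param seed Optional integer seed (deterministic output).
#' @return An `ape` `phylo` object with tip labels `t01, t02, ...`.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 2, seed = NULL) {
  if (n_taxa < 7) stop("n_taxa must be >= 7 (family-size filter)")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  with_seed(seed, {
    parent <- c(1L, 1L) # internal node (own numbering; 1 = root) of each lineage
    btime <- c(0, 0)
    n_int <- 1L
    ep <- integer(0); ec <- integer(0); el <- numeric(0)
    t_now <- 0
    while (length(parent) < n_taxa) {
      k <- length(parent)
      t_now <- t_now + stats::rexp(1, birth_rate * k)
      i <- sample.int(k, 1)
      n_int <- n_int + 1L
      ep <- c(ep, parent[i]); ec <- c(ec, n_int)
      el <- c(el, t_now - btime[i])
      parent[i] <- n_int; btime[i] <- t_now
      parent <- c(parent, n_int); btime <- c(btime, t_now)
    }
    t_end <- t_now + stats::rexp(1, birth_rate * n_taxa)
    n <- n_taxa
    edge <- rbind(cbind(n + ep, n + ec),
                  cbind(n + parent, seq_len(n)))
    len <- c(el, t_end - btime)
    tr <- list(edge = edge, edge.length = len,
               tip.label = sprintf("t%02d", seq_len(n)),
               Nnode = n_int)
    class(tr) <- "phylo"
    ape::reorder.phylo(tr, "cladewise")
  })
}

#' Evolve a protein family's sequences along a tree
#'
#' The root sequence is uniform over the 20 amino acids. Along each branch
#' of length t, every site is resampled from the 20-state Poisson
#' (Jukes-Cantor-like) transition kernel: it differs from its parent with
#' probability (19/20)(1 - exp(-(20/19) sub_rate t)), uniformly over the
#' other 19 letters. Indel events arrive as a Poisson process
#' (rate `indel_rate` per unit branch length); each is an insertion or a
#' deletion with equal probability, has geometric length, and a uniform
#' position (deletions never shrink a sequence below 10 residues). Every
#' residue carries a site identity through the tree, from which the true
#' multiple alignment is assembled.
#'
#' @param tree A `phylo` tree.
#' @param config A `synthetic_family_config`.
#' @return List with `alignment` (a `protein_alignment` over the true
#'   homology columns) and `genealogies` (per-node site identities and
#'   letters, plus the traversal-ordered tree), consumed by
#'   [build_structures()].
#' @export
evolve_family <- function(tree, config) {
  stopifnot(inherits(config, "synthetic_family_config"))
  tr <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  with_seed(config$seed + 1L, {
    L <- config$seq_length
    state <- vector("list", n_tip + tr$Nnode)
    state[[root]] <- list(letters = sample.int(20, L, replace = TRUE),
                          ids = seq_len(L))
    next_id <- L
    master <- seq_len(L)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]; t <- tr$edge.length[e]
      st <- state[[par]]
      p_diff <- (19 / 20) * (1 - exp(-(20 / 19) * config$sub_rate * t))
      hit <- stats::runif(length(st$letters)) < p_diff
      if (any(hit)) {
        shift <- sample.int(19, sum(hit), replace = TRUE)
        st$letters[hit] <- ((st$letters[hit] - 1L + shift) %% 20L) + 1L
      }
      nev <- stats::rpois(1, config$indel_rate * t)
      for (ev in seq_len(nev)) {
        len <- 1L + stats::rgeom(1, 1 / config$indel_len_mean)
        cur <- length(st$letters)
        if (stats::runif(1) < 0.5) { # deletion
          if (cur - len < 10) next
          start <- sample.int(cur - len + 1L, 1)
          idx <- start:(start + len - 1L)
          st$letters <- st$letters[-idx]
          st$ids <- st$ids[-idx]
        } else { # insertion after position pos (0 = before first residue)
          pos <- sample.int(cur + 1L, 1) - 1L
          anchor <- if (pos >= 1) st$ids[pos] else NA_integer_
          follower <- if (pos < cur) st$ids[pos + 1L] else NA_integer_
          new_ids <- next_id + seq_len(len)
          next_id <- next_id + len
          st$letters <- append(st$letters,
                               sample.int(20, len, replace = TRUE),
                               after = pos)
          st$ids <- append(st$ids, new_ids, after = pos)
          mpos <- if (!is.na(anchor)) match(anchor, master)
                  else match(follower, master) - 1L
          master <- append(master, new_ids, after = mpos)
        }
      }
      state[[chi]] <- st
    }
    leaf_ids <- lapply(seq_len(n_tip), function(i) state[[i]]$ids)
    used <- master[master %in% unique(unlist(leaf_ids))]
    col_of <- stats::setNames(seq_along(used), used)
    rows <- vapply(seq_len(n_tip), function(i) {
      row <- rep("-", length(used))
      row[col_of[as.character(state[[i]]$ids)]] <- AA_ALPHABET[state[[i]]$letters]
      paste(row, collapse = "")
    }, character(1))
    alignment <- structure(list(ids = tr$tip.label,
                                rows = stats::setNames(rows, tr$tip.label),
                                ncol = length(used)),
                           class = "protein_alignment")
    list(alignment = alignment,
         genealogies = list(node_ids = lapply(state, `[[`, "ids"),
                            node_letters = lapply(state, `[[`, "letters"),
                            tree = tr))
  })
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic compact helical root backbone. A coarse axis path (one knot
# per ~5 residues, 7.5 Angstrom steps) is confined to a ball of radius
# 3.0 * L^(1/3) (protein-like density, ~113 cubic Angstrom per residue)
# with ~8 Angstrom excluded volume between non-adjacent knots, emulating
# packed secondary-structure elements. An ideal helix (radius 2.3 Angstrom,
# 100 degrees per residue) is wound around the axis using a parallel-
# transported frame, and consecutive CA steps are renormalised to exactly
# 3.8 Angstrom. Local (helix-turn scale) topological features then occur at
# a size-independent density per residue, as in real globular proteins.
# Fully determined by the seed.
root_backbone <- function(L, seed) {
  with_seed(seed, {
    R <- 3.0 * L^(1 / 3)
    nk <- max(4L, ceiling(L / 5) + 1L)
    ax <- matrix(0, nk, 3)
    dir <- c(1, 0, 0)
    for (i in seq_len(nk)[-1]) {
      cand <- NULL
      for (att in 1:25) {
        pd <- dir + 0.6 * stats::rnorm(3)
        cand <- ax[i - 1, ] + 7.5 * pd / sqrt(sum(pd^2))
        if (sqrt(sum(cand^2)) > R) { # steer back into the ball
          pd <- pd - 1.5 * cand / sqrt(sum(cand^2))
          cand <- ax[i - 1, ] + 7.5 * pd / sqrt(sum(pd^2))
        }
        if (i <= 3) break
        dmin <- min(sqrt(rowSums(
          sweep(ax[seq_len(i - 2), , drop = FALSE], 2, cand)^2)))
        if (dmin > 8) break
      }
      ax[i, ] <- cand
      dir <- (cand - ax[i - 1, ]) / 7.5
    }
    t <- seq(1, nk, length.out = L)
    axi <- apply(ax, 2, function(cc) stats::approx(seq_len(nk), cc,
                                                   xout = t)$y)
    tang <- rbind(axi[2, ] - axi[1, ],
                  axi[-1, , drop = FALSE] - axi[-L, , drop = FALSE])
    tang <- tang / sqrt(rowSums(tang^2))
    u <- matrix(0, L, 3)
    w0 <- c(0, 0, 1) - sum(c(0, 0, 1) * tang[1, ]) * tang[1, ]
    if (sum(w0^2) < 1e-12) w0 <- c(0, 1, 0) -
        sum(c(0, 1, 0) * tang[1, ]) * tang[1, ]
    u[1, ] <- w0 / sqrt(sum(w0^2))
    for (i in seq_len(L)[-1]) { # parallel transport of the normal frame
      w <- u[i - 1, ] - sum(u[i - 1, ] * tang[i, ]) * tang[i, ]
      if (sum(w^2) < 1e-12) w <- u[i - 1, ]
      u[i, ] <- w / sqrt(sum(w^2))
    }
    v <- t(vapply(seq_len(L), function(i) cross3(tang[i, ], u[i, ]),
                  numeric(3)))
    ang <- (seq_len(L) - 1) * 100 / 180 * pi
    pts <- axi + 2.3 * (cos(ang) * u + sin(ang) * v)
    steps <- diff(pts)
    steps <- steps * (3.8 / sqrt(rowSums(steps^2)))
    unname(rbind(c(0, 0, 0), apply(steps, 2, cumsum)))
  })
}

make_structure <- function(id, coords, letters, confidence, sidechain = FALSE) {
  L <- nrow(coords)
  seq1 <- AA_ALPHABET[letters]
  res3 <- bio3d::aa123(seq1)
  rows <- list(data.frame(residue_index = seq_len(L), residue_name = res3,
                          atom_name = "CA", element = "C",
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          confidence = confidence,
                          stringsAsFactors = FALSE))
  if (sidechain) {
    i <- seq_len(L)
    d1 <- cbind(sin(1.7 * i), cos(1.7 * i), 0.8 * sin(0.9 * i))
    d1 <- d1 / sqrt(rowSums(d1^2))
    d2 <- cbind(cos(1.3 * i + 1), sin(2.1 * i), cos(0.7 * i))
    d2 <- d2 / sqrt(rowSums(d2^2))
    cb <- coords + 1.5 * d1
    het <- coords + 1.5 * d2
    het_name <- ifelse(i %% 2 == 1, "ND1", "OD1")
    het_elem <- ifelse(i %% 2 == 1, "N", "O")
    rows <- c(rows, list(
      data.frame(residue_index = i, residue_name = res3, atom_name = "CB",
                 element = "C", x = cb[, 1], y = cb[, 2], z = cb[, 3],
                 confidence = confidence, stringsAsFactors = FALSE),
      data.frame(residue_index = i, residue_name = res3, atom_name = het_name,
                 element = het_elem, x = het[, 1], y = het[, 2], z = het[, 3],
                 confidence = confidence, stringsAsFactors = FALSE)))
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$residue_index), , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms,
                 sequence = paste(seq1, collapse = "")),
            class = "protein_structure")
}

#' Build 3D structures for an evolved family
#'
#' The root backbone is a deterministic compact chain with 3.8 Angstrom
#' consecutive-CA spacing, confined at protein-like density (see
#' `root_backbone`). Coordinates evolve by Brownian motion along the
#' tree: each branch of length t adds i.i.d. Gaussian displacement of
#' standard deviation `struct_noise_sd * sqrt(t)` per coordinate to every
#' retained residue. Deleted residues disappear from descendants; inserted
#' residues are placed by linear interpolation between their flanking
#' residues (extrapolation along the chain direction at the termini) plus
#' the same Brownian-scale noise. Only CA atoms are emitted unless
#' `sidechain = TRUE`, which adds one dummy carbon and one alternating
#' nitrogen/oxygen atom per residue (offset 1.5 Angstrom) to exercise the
#' element selectors.
#'
#' @param tree The `phylo` tree the family evolved on.
#' @param alignment The alignment returned by [evolve_family()] (unused
#'   directly, kept for interface symmetry and validation).
#' @param genealogies The `genealogies` component of [evolve_family()].
#' @param config A `synthetic_family_config`.
#' @param sidechain Emit dummy side-chain atoms (default `FALSE`).
#' @return Named list of `protein_structure` objects, one per tip.
#' @export
build_structures <- function(tree, alignment, genealogies, config,
                             sidechain = FALSE) {
  tr <- genealogies$tree
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  with_seed(config$seed + 2L, {
    coords <- vector("list", n_tip + tr$Nnode)
    root_ids <- genealogies$node_ids[[root]]
    coords[[root]] <- root_backbone(length(root_ids), config$seed)
    rownames(coords[[root]]) <- root_ids
    sd0 <- config$struct_noise_sd
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]; t <- tr$edge.length[e]
      pids <- genealogies$node_ids[[par]]
      cids <- genealogies$node_ids[[chi]]
      pc <- coords[[par]]
      m <- length(cids)
      xyz <- matrix(NA_real_, m, 3)
      keep <- cids %in% pids
      if (any(keep)) {
        xyz[keep, ] <- pc[match(cids[keep], pids), , drop = FALSE] +
          matrix(stats::rnorm(3 * sum(keep), 0, sd0 * sqrt(t)), ncol = 3)
      }
      if (any(!keep)) {
        runs <- rle(keep)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        for (r in seq_along(runs$values)) {
          if (runs$values[r]) next
          i0 <- starts[r] - 1L; i1 <- ends[r] + 1L
          idx <- starts[r]:ends[r]
          len <- length(idx)
          noise <- matrix(stats::rnorm(3 * len, 0, sd0 * sqrt(t)), ncol = 3)
          if (i0 >= 1 && i1 <= m) {
            # inserted run protrudes as a loop: an arc between the flanks
            # whose length accommodates len extra residues at ~3.8 A spacing
            xL <- xyz[i0, ]; xR <- xyz[i1, ]
            chord <- xR - xL
            cl <- sqrt(sum(chord^2))
            bulge <- stats::rnorm(3)
            if (cl > 1e-9) bulge <- bulge - sum(bulge * chord) / cl^2 * chord
            bl <- sqrt(sum(bulge^2))
            if (bl < 1e-9) { bulge <- c(0, 0, 1); bl <- 1 }
            bulge <- bulge / bl
            height <- 3.8 * (len + 1) / pi # semicircle arc height
            frac <- seq_len(len) / (len + 1)
            xyz[idx, ] <- outer(1 - frac, xL) + outer(frac, xR) +
              outer(height * sin(pi * frac), bulge) + noise
          } else if (i1 <= m) { # N-terminal insertion: extend backwards
            dir <- if (i1 + 1L <= m && !anyNA(xyz[i1 + 1L, ]))
              xyz[i1, ] - xyz[i1 + 1L, ] else c(-3.8, 0, 0)
            dir <- dir / max(sqrt(sum(dir^2)), 1e-9) * 3.8
            xyz[rev(idx), ] <- xyz[rep(i1, len), ] +
              outer(seq_len(len), dir) + noise
          } else if (i0 >= 1) { # C-terminal insertion: extend forwards
            dir <- if (i0 - 1L >= 1 && !anyNA(xyz[i0 - 1L, ]))
              xyz[i0, ] - xyz[i0 - 1L, ] else c(3.8, 0, 0)
            dir <- dir / max(sqrt(sum(dir^2)), 1e-9) * 3.8
            xyz[idx, ] <- xyz[rep(i0, len), ] +
              outer(seq_len(len), dir) + noise
          } else stop("internal error: empty parent sequence")
        }
      }
      rownames(xyz) <- cids
      coords[[chi]] <- xyz
    }
    structures <- lapply(seq_len(n_tip), function(i) {
      make_structure(tr$tip.label[i], unname(coords[[i]]),
                     genealogies$node_letters[[i]],
                     confidence = rep(95, nrow(coords[[i]])),
                     sidechain = sidechain)
    })
    stats::setNames(structures, tr$tip.label)
  })
}

#' Assign per-residue confidence indices
#'
#' A random fraction of residues is flagged low-confidence (index drawn
#' uniformly in \[40, 70)); the rest receive an index in \[85, 99\]. Low-CI
#' residues additionally receive extra coordinate noise (`extra_noise_sd`
#' per coordinate, applied rigidly to all atoms of the residue), so that
#' confidence masking measurably improves the structural signal.
#'
#' @param structures Named list of `protein_structure` objects.
#' @param low_ci_fraction Probability that a residue is low-confidence.
#' @param seed Optional integer seed.
#' @param extra_noise_sd Extra displacement (Angstrom, per coordinate) for
#'   low-CI residues; a scalar or one value per structure. The generator
#'   passes the displacement a residue would accumulate if its Brownian
#'   noise were tripled along the root-to-leaf path,
#'   `sqrt(8) * struct_noise_sd * sqrt(leaf depth)`.
#' @param low_flags Optional list (one logical vector per structure, over
#'   its residues) marking which residues are low-confidence. The generator
#'   derives these from family-wide homologous sites: low-confidence
#'   regions (flexible loops, termini) are a property of aligned positions,
#'   not of individual structures. Default: independent Bernoulli draws per
#'   residue.
#' @return The structures with confidence set (and low-CI coordinates
#'   perturbed).
#' @export
assign_confidence <- function(structures, low_ci_fraction, seed = NULL,
                              extra_noise_sd = 0, low_flags = NULL) {
  if (low_ci_fraction < 0 || low_ci_fraction > 1)
    stop("low_ci_fraction must be in [0, 1]")
  xsd_all <- rep_len(extra_noise_sd, length(structures))
  with_seed(seed, {
    out <- lapply(seq_along(structures), function(i) {
      s <- structures[[i]]
      xsd <- xsd_all[i]
      res <- unique(s$atoms$residue_index)
      low <- if (!is.null(low_flags)) rep_len(low_flags[[i]], length(res))
             else stats::runif(length(res)) < low_ci_fraction
      conf <- ifelse(low, stats::runif(length(res), 40, 70 - 1e-9),
                     stats::runif(length(res), 85, 99))
      names(conf) <- as.character(res)
      s$atoms$confidence <- unname(conf[as.character(s$atoms$residue_index)])
      if (xsd > 0 && any(low)) {
        shift <- matrix(stats::rnorm(3 * sum(low), 0, xsd),
                        ncol = 3, dimnames = list(as.character(res[low])))
        hit <- s$atoms$residue_index %in% res[low]
        key <- as.character(s$atoms$residue_index[hit])
        s$atoms$x[hit] <- s$atoms$x[hit] + shift[key, 1]
        s$atoms$y[hit] <- s$atoms$y[hit] + shift[key, 2]
        s$atoms$z[hit] <- s$atoms$z[hit] + shift[key, 3]
      }
      s
    })
    stats::setNames(out, names(structures))
  })
}

#' Simulate a complete synthetic protein family
#'
#' Chains [simulate_tree()], [evolve_family()], [build_structures()] and
#' [assign_confidence()] into a `family_bundle`: the unit the pipeline
#' consumes (structures + alignment + tree + true patristic distances).
#'
#' @param config A `synthetic_family_config` (or arguments passed to it).
#' @param id Family identifier.
#' @param sidechain Emit dummy side-chain atoms.
#' @return A `family_bundle`: list with `id`, `tree`, `alignment`,
#'   `structures`, `truth` (true patristic matrix) and `config`.
#' @export
simulate_family <- function(config = synthetic_family_config(), id = "fam1",
                            sidechain = FALSE) {
  stopifnot(inherits(config, "synthetic_family_config"))
  tree <- simulate_tree(config$n_taxa, config$birth_rate, config$seed)
  ev <- evolve_family(tree, config)
  structures <- build_structures(tree, ev$alignment, ev$genealogies, config,
                                 sidechain = sidechain)
  # low-CI residues behave as if their Brownian noise were tripled along the
  # root-to-leaf path: extra displacement sd = sqrt(9 - 1) * sd0 * sqrt(depth)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depths) <- tree$tip.label
  # low-confidence status is drawn once per homologous site (family-wide):
  # disordered regions are shared across homologs
  all_ids <- sort(unique(unlist(ev$genealogies$node_ids)))
  low_sites <- with_seed(config$seed + 4L,
                         all_ids[stats::runif(length(all_ids)) <
                                 config$low_ci_fraction])
  tips <- names(structures)
  tip_idx <- match(tips, ev$genealogies$tree$tip.label)
  low_flags <- lapply(tip_idx, function(i)
    ev$genealogies$node_ids[[i]] %in% low_sites)
  structures <- assign_confidence(structures, config$low_ci_fraction,
                                  seed = config$seed + 3L,
                                  extra_noise_sd = sqrt(8) *
                                    config$struct_noise_sd *
                                    sqrt(depths[tips]),
                                  low_flags = low_flags)
  structure(list(id = id, tree = tree, alignment = ev$alignment,
                 structures = structures,
                 truth = patristic_matrix(tree), config = config),
            class = "family_bundle")
}

#' @export
print.family_bundle <- function(x, ...) {
  cat("<family_bundle>", x$id, "-", length(x$structures), "structures,",
      "alignment", x$alignment$ncol, "columns\n")
  invisible(x)
}

#' Simulate a heterogeneous set of protein families
#'
#' Generates `n_families` synthetic families whose evolutionary depths vary
#' widely: each family draws its Yule rate log-uniformly from
#' `divergence_range` (larger rate = shallower tree = less divergence).
#' This emulates study sets that pool families from taxa of very different
#' genetic divergence, where between-family divergence spread dominates the
#' pooled distance distribution.
#'
#' @param n_families Number of families.
#' @param seed Master seed; family i uses `seed + i`.
#' @param seq_lengths Vector recycled over families.
#' @param n_taxa Vector recycled over families.
#' @param divergence_range Range of the per-family Yule rate.
#' @param ... Further arguments passed to [synthetic_family_config()].
#' @return List of `family_bundle`s named `fam01, fam02, ...`.
#' @export
simulate_family_set <- function(n_families, seed = 1L, seq_lengths = 80,
                                n_taxa = 10, divergence_range = c(0.7, 7),
                                ...) {
  seq_lengths <- rep_len(seq_lengths, n_families)
  n_taxa <- rep_len(n_taxa, n_families)
  rates <- with_seed(seed, exp(stats::runif(n_families,
                                            log(divergence_range[1]),
                                            log(divergence_range[2]))))
  out <- lapply(seq_len(n_families), function(i) {
    cfg <- synthetic_family_config(n_taxa = n_taxa[i],
                                   seq_length = seq_lengths[i],
                                   birth_rate = rates[i],
                                   seed = seed + i, ...)
    simulate_family(cfg, id = sprintf("fam%02d", i))
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "id"))
}

#' Write a family bundle to disk
#'
#' One PDB file per structure (confidence in the B-factor column), the
#' alignment as aligned FASTA, the tree as Newick, and the true patristic
#' matrix as CSV.
#'
#' @param bundle A `family_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in bundle$structures) {
    at <- s$atoms
    bio3d::write.pdb(file = file.path(dir, paste0(s$id, ".pdb")),
                     xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                     resno = at$residue_index, resid = at$residue_name,
                     elety = at$atom_name, elesy = at$element,
                     b = round(at$confidence, 2), chain = "A")
  }
  writeLines(paste0(">", bundle$alignment$ids, "\n",
                    bundle$alignment$rows[bundle$alignment$ids]),
             file.path(dir, "alignment.fasta"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(bundle$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a family bundle from disk
#'
#' @param dir Directory written by [write_family_bundle()].
#' @param id Family identifier (default the directory name).
#' @return A `family_bundle` (without the generating config).
#' @export
read_family_bundle <- function(dir, id = basename(dir)) {
  pdbs <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  structures <- lapply(pdbs, read_structure)
  names(structures) <- vapply(structures, `[[`, character(1), "id")
  truth <- as.matrix(utils::read.csv(file.path(dir, "truth.csv"),
                                     row.names = 1, check.names = FALSE))
  structure(list(id = id,
                 tree = read_newick(file.path(dir, "tree.nwk")),
                 alignment = read_alignment(file.path(dir, "alignment.fasta")),
                 structures = structures,
                 truth = truth, config = NULL),
            class = "family_bundle")
}
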