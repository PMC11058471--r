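ph_metrics <- c("btk", "ws", "ls")

# Barcode (and landscape) cache keyed by structure id + retained residues:
# under pair-specific indel masking the same structure yields different
# clouds depending on its partner, so caching is keyed by the retained set.
bars_for_cloud <- function(cache, id, cloud, filtration, dims, need_landscape,
                           vr_threshold = NULL) {
  key <- paste(id, filtration, paste(cloud$residue_of_point, collapse = ","),
               sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit) && (!need_landscape || !is.null(hit$landscapes)))
    return(hit)
  fc <- if (filtration == "AC") build_alpha_complex(cloud)
        else build_vietoris_rips(cloud, threshold = vr_threshold)
  bars <- compute_persistence(fc, dims)
  out <- list(bars = bars, n = cloud$n)
  if (need_landscape)
    out$landscapes <- lapply(bars, build_landscape)
  cache[[key]] <- out
  out
}

#' Compute the PH-distance table of a protein family
#'
#' For every unordered pair of structures in the family, applies the
#' requested masking (confidence and/or pair-specific indel masking),
#' builds one filtration per masked cloud, computes barcodes in homological
#' dimensions 1 and 2, and evaluates the requested distances (bottleneck,
#' Wasserstein, landscape). Raw distances and distances normalized by the
#' average number of points actually used are both recorded.
#'
#' @param bundle A `family_bundle`.
#' @param filtration `"AC"` (alpha complex, default) or `"VR"`.
#' @param metrics Subset of `c("btk", "ws", "ls")`.
#' @param dims Homological dimensions (subset of `1:2`).
#' @param selector Atom selector for the point clouds (see
#'   [extract_point_cloud()]).
#' @param masking One of `"none"`, `"ci"`, `"indel"`, `"ci+indel"`.
#' @param ci_threshold,ci_strict Confidence masking parameters.
#' @param ws_root Use the rooted Wasserstein metric (`TRUE`) or the raw
#'   minimal sum of squared matched costs (`FALSE`, default): the latter
#'   scales linearly with point count, which is what the point-count
#'   normalization assumes.
#' @param vr_threshold Optional VR threshold (default: cloud diameter).
#' @param min_structures Minimum family size (default 7).
#' @return A data.frame (`DistanceTable`) in long format: `family_id`,
#'   `idA`, `idB`, `metric`, `k`, `filtration`, `selector`, `masking`,
#'   `raw`, `normalized`, `nA`, `nB`, `gap_count`.
#' @export
family_ph_distances <- function(bundle, filtration = c("AC", "VR"),
                                metrics = c("btk", "ws", "ls"),
                                dims = 1:2, selector = "CA",
                                masking = c("none", "ci", "indel", "ci+indel"),
                                ci_threshold = 70, ci_strict = FALSE,
                                ws_root = FALSE, vr_threshold = NULL,
                                min_structures = 7) {
  stopifnot(inherits(bundle, "family_bundle"))
  filtration <- match.arg(filtration)
  masking <- match.arg(masking)
  metrics <- match.arg(metrics, ph_metrics, several.ok = TRUE)
  ids <- names(bundle$structures)
  if (length(ids) < min_structures)
    stop("family has fewer than ", min_structures, " structures")
  use_ci <- masking %in% c("ci", "ci+indel")
  use_indel <- masking %in% c("indel", "ci+indel")
  have_aln <- !is.null(bundle$alignment)
  if (use_indel && !have_aln) stop("indel masking requires an alignment")

  clouds <- lapply(ids, function(id) {
    s <- bundle$structures[[id]]
    pc <- extract_point_cloud(s, selector)
    if (use_ci) pc <- mask_low_confidence(pc, s, ci_threshold, ci_strict)
    pc
  })
  names(clouds) <- ids

  cache <- new.env(parent = emptyenv())
  need_ls <- "ls" %in% metrics
  prs <- utils::combn(ids, 2)
  rows <- vector("list", ncol(prs))
  for (p in seq_len(ncol(prs))) {
    a <- prs[1, p]; b <- prs[2, p]
    cA <- clouds[[a]]; cB <- clouds[[b]]
    gap_count <- NA_integer_
    if (have_aln) {
      pm <- pair_indel_map(bundle$alignment, a, b)
      gap_count <- pm$gap_count
      if (use_indel) {
        mk <- mask_indel_residues(cA, cB, pm)
        cA <- mk$A; cB <- mk$B
      }
    }
    res <- tryCatch({
      bA <- bars_for_cloud(cache, a, cA, filtration, dims, need_ls, vr_threshold)
      bB <- bars_for_cloud(cache, b, cB, filtration, dims, need_ls, vr_threshold)
      out <- list()
      for (k in dims) {
        hk <- paste0("H", k)
        for (metric in metrics) {
          raw <- switch(metric,
            btk = bottleneck_distance(bA$bars[[hk]], bB$bars[[hk]]),
            ws = wasserstein_distance(bA$bars[[hk]], bB$bars[[hk]],
                                      root = ws_root),
            ls = landscape_distance(bA$landscapes[[hk]], bB$landscapes[[hk]]))
          out[[length(out) + 1]] <- data.frame(
            family_id = bundle$id, idA = a, idB = b, metric = metric, k = k,
            filtration = filtration, selector = selector, masking = masking,
            raw = raw, normalized = normalize_distance(raw, bA$n, bB$n),
            nA = bA$n, nB = bB$n, gap_count = gap_count,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, out)
    }, error = function(e) {
      warning("skipping pair ", a, "-", b, ": ", conditionMessage(e))
      NULL
    })
    rows[[p]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pair could be computed")
  rownames(out) <- NULL
  out
}

#' Evolutionary distance matrices of a family
#'
#' @param bundle A `family_bundle` with alignment and tree covering the
#'   same identifiers as the structures.
#' @return List with `p` (observed p-distance matrix from the untrimmed
#'   alignment) and `ml` (patristic distance matrix from the tree), both
#'   keyed by structure id.
#' @export
family_ev_distances <- function(bundle) {
  stopifnot(inherits(bundle, "family_bundle"))
  ids <- names(bundle$structures)
  if (!setequal(ids, bundle$alignment$ids) ||
      !setequal(ids, bundle$tree$tip.label))
    stop("id mismatch between structures, alignment and tree")
  n <- length(ids)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p[i, j] <- p[j, i] <- p_distance(bundle$alignment, ids[i], ids[j])
    }
  }
  ml <- patristic_matrix(bundle$tree)[ids, ids]
  list(p = p, ml = ml)
}

#' Pearson correlation between paired distance vectors
#'
#' Pearson's r with its parametric t-test p-value and, optionally, a
#' Mantel-style permutation p-value that honours the non-independence of
#' pairwise distances: protein labels are permuted within families and the
#' correlation recomputed.
#'
#' @param x,y Equal-length numeric vectors of paired distances.
#' @param permutations Number of label permutations (0 = none).
#' @param pair_ids For permutations: data.frame with columns `family`,
#'   `idA`, `idB`, one row per element of `x`.
#' @param alternative `"greater"` (default; a positive association is the
#'   scientific hypothesis) or `"two.sided"` for the permutation test.
#' @param grouping Label stored in the result.
#' @param seed Optional seed for the permutations.
#' @return A `correlation_result`: list with `r`, `p_t`, `p_perm`,
#'   `n_pairs`, `grouping`.
#' @export
correlate_distances <- function(x, y, permutations = 0, pair_ids = NULL,
                                alternative = c("greater", "two.sided"),
                                grouping = "all", seed = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("undefined correlation")
  ct <- stats::cor.test(x, y)
  r_obs <- unname(ct$estimate)
  p_perm <- NA_real_
  if (permutations > 0) {
    if (is.null(pair_ids) || !all(c("family", "idA", "idB") %in% names(pair_ids)))
      stop("permutations require pair_ids with family, idA, idB")
    if (nrow(pair_ids) != length(x)) stop("pair_ids must match x")
    fams <- split(seq_along(x), pair_ids$family)
    fam_ids <- lapply(fams, function(idx)
      sort(unique(c(pair_ids$idA[idx], pair_ids$idB[idx]))))
    p_perm <- with_seed(seed, {
      hits <- 0
      for (b in seq_len(permutations)) {
        yp <- y
        for (f in names(fams)) {
          idx <- fams[[f]]
          labs <- fam_ids[[f]]
          perm <- stats::setNames(sample(labs), labs)
          # value of the permuted pair, looked up in the original table
          key0 <- paste(pmin(pair_ids$idA[idx], pair_ids$idB[idx]),
                        pmax(pair_ids$idA[idx], pair_ids$idB[idx]))
          lut <- stats::setNames(y[idx], key0)
          a2 <- perm[pair_ids$idA[idx]]; b2 <- perm[pair_ids$idB[idx]]
          yp[idx] <- unname(lut[paste(pmin(a2, b2), pmax(a2, b2))])
        }
        rb <- stats::cor(x, yp)
        hits <- hits + if (alternative == "greater") (rb >= r_obs)
                       else (abs(rb) >= abs(r_obs))
      }
      (1 + hits) / (permutations + 1)
    })
  }
  structure(list(r = r_obs, p_t = ct$p.value, p_perm = p_perm,
                 n_pairs = length(x), grouping = grouping),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: r = %.3f (n = %d, p_t = %.3g%s)\n",
              x$grouping, x$r, x$n_pairs, x$p_t,
              if (!is.na(x$p_perm)) sprintf(", p_perm = %.3g", x$p_perm)
              else ""))
  invisible(x)
}

#' Correlation of PH-distances with point count
#'
#' Checks how strongly a distance column of a `DistanceTable` correlates
#' with the average number of points of the compared clouds. Raw
#' PH-distances correlate strongly with size; normalized ones should not.
#'
#' @param table A `DistanceTable` (typically filtered to one metric/k).
#' @param use_normalized Correlate the normalized (default) or raw column.
#' @return A `correlation_result` (two-sided permutationless test).
#' @export
size_correlation_check <- function(table, use_normalized = TRUE) {
  if (nrow(table) == 0) stop("empty distance table")
  x <- (table$nA + table$nB) / 2
  y <- if (use_normalized) table$normalized else table$raw
  correlate_distances(x, y,
                      grouping = if (use_normalized) "normalized~size"
                                 else "raw~size")
}

#' Gap-stratified correlation between PH- and EV-distances
#'
#' Splits the pairs by the number of single-gap alignment columns between
#' the two sequences and reports the correlation of normalized PH-distance
#' with evolutionary distance per stratum. With unmasked indels the
#' correlation degrades as the gap count grows; indel masking removes the
#' effect.
#'
#' @param table A `DistanceTable` filtered to one metric/k/configuration.
#' @param ev_matrix Evolutionary distance matrix keyed by structure id, or
#'   (for tables pooling several families) a named list of such matrices
#'   keyed by `family_id`.
#' @param bins Left edges of the gap-count bins (last bin open-ended).
#' @return Named list of `correlation_result`s (bins with fewer than 3
#'   pairs are dropped with a warning).
#' @export
gap_stratified_correlation <- function(table, ev_matrix,
                                       bins = c(0, 1, 10, 50)) {
  if (anyNA(table$gap_count)) stop("gap_count not populated")
  breaks <- c(bins, Inf)
  labels <- vapply(seq_along(bins), function(i) {
    lo <- bins[i]
    hi <- if (i < length(bins)) bins[i + 1] - 1 else Inf
    if (lo >= hi) as.character(lo)
    else if (is.infinite(hi)) paste0(lo, "+")
    else paste0(lo, "-", hi)
  }, character(1))
  bin_of <- cut(table$gap_count, breaks = breaks, labels = labels,
                right = FALSE, include.lowest = TRUE)
  ev_of <- function(idx) {
    if (is.list(ev_matrix) && !is.matrix(ev_matrix)) {
      vapply(idx, function(i)
        ev_matrix[[table$family_id[i]]][table$idA[i], table$idB[i]],
        numeric(1))
    } else {
      ev_matrix[cbind(table$idA[idx], table$idB[idx])]
    }
  }
  out <- list()
  for (lb in levels(droplevels(bin_of))) {
    idx <- which(bin_of == lb)
    if (length(idx) < 3) {
      warning("dropping gap bin '", lb, "' with ", length(idx), " pair(s)")
      next
    }
    ev <- ev_of(idx)
    out[[lb]] <- tryCatch(
      correlate_distances(ev, table$normalized[idx],
                          grouping = paste0("gaps:", lb)),
      error = function(e) {
        warning("dropping gap bin '", lb, "': ", conditionMessage(e))
        NULL
      })
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Homologous versus nonhomologous PH-distance null comparison
#'
#' Samples pairs of structures within families (homologous) and across
#' families (nonhomologous), computes their normalized PH-distances, and
#' tests one-sided (Wilcoxon rank-sum) whether nonhomologous distances are
#' larger — i.e. whether homologous PH-distances could have been observed
#' by chance alone.
#'
#' @param families List of at least two `family_bundle`s.
#' @param n_pairs Number of pairs per group.
#' @param seed Seed for the pair sampling.
#' @param filtration,metric,k,selector,ws_root Distance configuration
#'   (defaults: Wasserstein, alpha complex, dimension 1, CA cloud).
#' @return A `homolog_null`: list with the two distance vectors, their
#'   summaries, and the `htest` result.
#' @export
homolog_null_comparison <- function(families, n_pairs = 500, seed = 1,
                                    filtration = "AC", metric = "ws", k = 1,
                                    selector = "CA", ws_root = FALSE) {
  if (length(families) < 2) stop("need at least 2 families")
  metric <- match.arg(metric, ph_metrics)
  fam_ids <- vapply(families, `[[`, character(1), "id")
  if (anyDuplicated(fam_ids)) stop("duplicate family ids")
  names(families) <- fam_ids

  within <- do.call(rbind, lapply(families, function(bd) {
    prs <- utils::combn(names(bd$structures), 2)
    data.frame(family_A = bd$id, idA = prs[1, ], family_B = bd$id,
               idB = prs[2, ], stringsAsFactors = FALSE)
  }))
  with_seed(seed, {
    wsel <- sample.int(nrow(within), n_pairs,
                       replace = nrow(within) < n_pairs)
    hom <- within[wsel, , drop = FALSE]
    fpair <- matrix(fam_ids[t(vapply(seq_len(n_pairs), function(i)
      sample.int(length(families), 2), integer(2)))], ncol = 2)
    nonhom <- data.frame(
      family_A = fpair[, 1],
      idA = vapply(fpair[, 1], function(f)
        sample(names(families[[f]]$structures), 1), character(1)),
      family_B = fpair[, 2],
      idB = vapply(fpair[, 2], function(f)
        sample(names(families[[f]]$structures), 1), character(1)),
      stringsAsFactors = FALSE)

    cache <- new.env(parent = emptyenv())
    need_ls <- metric == "ls"
    hk <- paste0("H", k)
    one <- function(fam, id) {
      pc <- extract_point_cloud(families[[fam]]$structures[[id]], selector)
      bars_for_cloud(cache, paste(fam, id), pc, filtration, k, need_ls)
    }
    dist_of <- function(tab) {
      vapply(seq_len(nrow(tab)), function(i) {
        a <- one(tab$family_A[i], tab$idA[i])
        b <- one(tab$family_B[i], tab$idB[i])
        raw <- switch(metric,
          btk = bottleneck_distance(a$bars[[hk]], b$bars[[hk]]),
          ws = wasserstein_distance(a$bars[[hk]], b$bars[[hk]],
                                    root = ws_root),
          ls = landscape_distance(a$landscapes[[hk]], b$landscapes[[hk]]))
        normalize_distance(raw, a$n, b$n)
      }, numeric(1))
    }
    d_hom <- dist_of(hom)
    d_non <- dist_of(nonhom)
    test <- stats::wilcox.test(d_non, d_hom, alternative = "greater",
                               exact = FALSE)
    structure(list(homologous = d_hom, nonhomologous = d_non,
                   summary = data.frame(
                     group = c("homologous", "nonhomologous"),
                     n = c(length(d_hom), length(d_non)),
                     median = c(stats::median(d_hom), stats::median(d_non)),
                     mean = c(mean(d_hom), mean(d_non))),
                   test = test),
              class = "homolog_null")
  })
}

#' @export
print.homolog_null <- function(x, ...) {
  print(x$summary)
  cat(sprintf("one-sided rank-sum (nonhomologous > homologous): p = %.3g\n",
              x$test$p.value))
  invisible(x)
}

parse_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config)) {
    lines <- readLines(config)
    lines <- sub("#.*$", "", lines)
    lines <- lines[grepl("=", lines)]
    kv <- strsplit(lines, "=")
    cfg <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
    names(cfg) <- vapply(kv, function(p) trimws(p[1]), character(1))
    cfg
  } else if (is.list(config)) config
  else stop("config must be a file path or a named list")
}

#' Run the full per-family pipeline
#'
#' Generates (or loads) family bundles, computes PH- and EV-distance
#' tables, pools the normalized PH-distances against the evolutionary
#' distances, and writes CSV tables plus a JSON correlation report.
#'
#' @param config A named list or a path to a flat `key = value` file.
#'   Recognised keys: `family_dirs` (semicolon-separated bundle
#'   directories) or `n_families` plus any [synthetic_family_config()]
#'   field; `seed`; `filtration`; `metrics` (comma-separated); `masking`;
#'   `selector`; `permutations`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly. Writes `distances.csv`,
#'   `ev_<p|ml>_<family>.csv`, `correlations.json` and `pipeline.log`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- parse_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  seed <- as.integer(cfg$seed %||% 1L)
  filtration <- cfg$filtration %||% "AC"
  masking <- cfg$masking %||% "none"
  selector <- cfg$selector %||% "CA"
  metrics <- strsplit(cfg$metrics %||% "ws", ",")[[1]]
  permutations <- as.integer(cfg$permutations %||% 0L)

  if (!is.null(cfg$family_dirs)) {
    dirs <- strsplit(cfg$family_dirs, ";")[[1]]
    if (length(dirs) == 0) stop("empty family list")
    bundles <- lapply(dirs, read_family_bundle)
  } else {
    nf <- as.integer(cfg$n_families %||% 0L)
    if (nf < 1) stop("empty family list: set family_dirs or n_families")
    synth_keys <- intersect(names(cfg),
                            setdiff(names(formals(synthetic_family_config)),
                                    "seed"))
    bundles <- lapply(seq_len(nf), function(i) {
      args <- lapply(cfg[synth_keys], function(v) as.numeric(v))
      args$seed <- seed + i
      simulate_family(do.call(synthetic_family_config, args),
                      id = sprintf("fam%02d", i))
    })
    log("simulated ", nf, " families (seed ", seed, ")")
  }

  tables <- list(); evs <- list()
  for (bd in bundles) {
    res <- tryCatch({
      tab <- family_ph_distances(bd, filtration = filtration,
                                 metrics = metrics, masking = masking,
                                 selector = selector)
      ev <- family_ev_distances(bd)
      list(tab = tab, ev = ev)
    }, error = function(e) {
      log("family ", bd$id, " FAILED: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    tables[[bd$id]] <- res$tab
    evs[[bd$id]] <- res$ev
    utils::write.csv(res$ev$p,
                     file.path(out_dir, paste0("ev_p_", bd$id, ".csv")))
    utils::write.csv(res$ev$ml,
                     file.path(out_dir, paste0("ev_ml_", bd$id, ".csv")))
    log("family ", bd$id, ": ", nrow(res$tab), " distance records")
  }
  if (length(tables) == 0) stop("all families failed")
  table <- do.call(rbind, tables)
  rownames(table) <- NULL
  utils::write.csv(table, file.path(out_dir, "distances.csv"),
                   row.names = FALSE)

  report <- list()
  for (metric in unique(table$metric)) {
    for (k in unique(table$k)) {
      sub <- table[table$metric == metric & table$k == k, , drop = FALSE]
      for (evkind in c("p", "ml")) {
        ev <- unlist(lapply(names(evs), function(f) {
          s <- sub[sub$family_id == f, , drop = FALSE]
          evs[[f]][[evkind]][cbind(s$idA, s$idB)]
        }))
        sub_all <- sub[sub$family_id %in% names(evs), , drop = FALSE]
        cr <- tryCatch(correlate_distances(
          ev, sub_all$normalized, permutations = permutations,
          pair_ids = data.frame(family = sub_all$family_id,
                                idA = sub_all$idA, idB = sub_all$idB),
          grouping = paste(metric, k, evkind, sep = "_"), seed = seed),
          error = function(e) NULL)
        if (!is.null(cr)) report[[cr$grouping]] <- unclass(cr)
      }
    }
  }
  jsonlite::write_json(report, file.path(out_dir, "correlations.json"),
                       auto_unbox = TRUE, digits = NA)
  log("wrote ", file.path(out_dir, "correlations.json"))
  invisible(out_dir)
}
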