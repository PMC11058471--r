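Package: phsignal
Title: Phylogenetic Signal in Protein 3D Structures via Persistent Homology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measures the phylogenetic signal carried by protein 3D structures
    using persistent homology. Protein structures are turned into atom point
    clouds, filtered with Vietoris-Rips or alpha-complex filtrations, and
    summarised as barcodes and persistence landscapes in homological
    dimensions 1 and 2. Barcodes are compared with bottleneck, Wasserstein and
    landscape distances, normalized by point count, and correlated with
    evolutionary distances derived from multiple sequence alignments
    (p-distances) and phylogenetic trees (patristic distances). Includes
    per-residue confidence masking, pair-specific indel masking, a
    homolog-versus-nonhomolog null comparison, and a synthetic generator of
    protein families whose sequences and structures diverge together along a
    tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
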