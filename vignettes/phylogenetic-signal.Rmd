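---
title: "Measuring phylogenetic signal in protein structures with persistent homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetic signal in protein structures with persistent homology}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phsignal)
```

## The question

Homologous proteins accumulate substitutions, insertions and deletions as
they diverge, and these sequence changes deform their 3D structures. If the
geometric deformation tracks the evolutionary divergence, then distances
computed purely from structure should correlate with distances computed
from sequences and trees — structures would carry a usable phylogenetic
signal. `phsignal` measures that signal with persistent homology (PH), an
approach that characterises a structure by the multiscale behaviour of its
cycles (homological dimension k = 1) and cavities (k = 2) without requiring
any structural alignment or point correspondence between the proteins being
compared.

## The pipeline

For each protein the atoms of interest (alpha carbons by default; all
atoms, or all C/N/O atoms, as alternatives) form a 3D point cloud. A growing
spatial scale parameter turns the cloud into a filtered simplicial complex
under one of two constructions:

* **Vietoris–Rips (VR)**: a simplex enters when the maximum pairwise
  distance among its vertices (its diameter) reaches the scale. Values are
  in Angstrom. Simplices are built to dimension 3 so that k = 2 homology is
  computable, and the default threshold is the cloud diameter so every
  positive-dimensional class dies.
* **Alpha complex (AC)**: simplices of the 3D Delaunay triangulation,
  entering at the squared radius of their smallest empty circumscribing
  ball (Gabriel simplices at their squared circumradius, other faces at the
  minimum of their cofaces). Values are in squared Angstrom. AC complexes
  are linear in the number of points and are the default for proteins.

Because the two filtrations are expressed in different units (Angstrom vs
squared Angstrom), VR- and AC-derived distances are never mixed in one
correlation.

Persistence is computed by the standard boundary-matrix reduction over the
field with two elements, with the twist (clearing) optimisation. Ties in
filtration value are broken by (dimension, lexicographic vertex tuple);
any tie-break yields the same barcode, a fixed one makes runs bit-for-bit
reproducible. Dimension-0 classes reflect inter-point spacing rather than
intrinsic shape and are excluded from the pipeline output (they remain
available for diagnostics).

Barcodes are compared with three distances:

* **Bottleneck**: the largest L-infinity displacement under the optimal
  augmented matching (unmatched intervals pay half their persistence).
  Computed exactly by binary search over the candidate cost set with
  bipartite-matching feasibility tests.
* **Wasserstein (q = 2, internal p = 2)**: the minimal sum of squared
  Euclidean displacements under an augmented optimal assignment, solved
  exactly with a Hungarian algorithm on the (|P|+|Q|)-sized matrix.
* **Landscape (p = 2)**: the L2 distance between persistence landscapes,
  represented exactly by breakpoints and integrated in closed form
  piecewise (no grid error anywhere in the construction).

### The Wasserstein convention used by the pipeline

`wasserstein_distance()` returns by default the square root of the minimal
sum of squares — the metric W2, which satisfies the triangle inequality and
the bottleneck lower bound. The *pipeline*, however, records the raw
minimal sum of squares (`ws_root = FALSE`). Two reasons, both visible in
the data rather than matters of taste:

1. Under Brownian structural divergence the expected sum of squared
   matched costs grows linearly in the divergence time, so the un-rooted
   quantity is the natural (linear) estimator of evolutionary distance;
   the rooted form compresses the scale as the square root.
2. Only the un-rooted form scales linearly with the number of points, which
   is exactly what dividing by the average point count assumes. With the
   rooted form, normalized distances would decrease systematically as
   proteins get longer and the normalization would fail at its only job.

### Normalization and masking

Raw PH-distances grow with protein size, so all comparisons use distances
divided by the average number of points actually used in the two clouds
(`normalize_distance()`). Two maskings address known nuisance factors:

* **Confidence masking** removes whole residues whose per-residue
  confidence index (pLDDT stored in the PDB B-factor column) is below 70.
  The comparison is `>= 70` by default with a strictness switch.
* **Indel masking** removes, per pair, the residues sitting opposite a gap
  in the pairwise restriction of the family alignment. It is pair-specific:
  the same structure keeps different points depending on its partner, so
  barcodes are cached keyed by (structure, retained-residue set).

The two maskings commute (each is an intersection on the retained residue
set), which the test suite checks.

### Evolutionary distances

Sequence divergence is measured two ways: the observed **p-distance**
(proportion of differing sites among columns where neither sequence is
gapped — pairwise deletion — on the untrimmed alignment), and the
**patristic distance** (path length between leaves on the tree, in
expected substitutions per site). Trees and alignments are inputs; the
package neither aligns nor infers trees.

## The synthetic family generator

Real protein families with predicted structures are large external
datasets; the generator produces families with the statistical structure
the analysis assumes, so every stage is testable from scratch.

* **Tree**: a pure-birth (Yule) process started from two lineages, run to
  `n_taxa` tips (at least 7, mirroring the usual family-size floor),
  ultrametric with exponential waiting times. `birth_rate` sets the depth
  (roughly `log(n_taxa)/birth_rate`).
* **Sequences**: the root is uniform over the 20 amino acids; along each
  branch every site is resampled from the 20-state Poisson (Jukes–Cantor
  style) transition kernel, which composes exactly across branches and
  gives the closed-form expected p-distance
  (19/20)(1 − exp(−(20/19) d)) at patristic distance d — verified by
  simulation at 1000 sites. Indel events arrive as a Poisson process per
  branch (`indel_rate` per unit length), half insertions half deletions,
  geometric lengths (`indel_len_mean`), uniform positions. Site identities
  are tracked through the tree, so the true alignment is known exactly.
* **Root fold**: a deterministic compact helical bundle — an ideal helix
  (2.3 A radius, 100 degrees per residue) wound along a seeded random axis
  confined to a ball at protein-like density (3.0 L^(1/3) A radius, about
  113 cubic Angstrom per residue), with consecutive CA spacing exactly
  3.8 A. The confinement matters: it makes topological feature density per
  residue nearly size-independent, as in globular proteins, so that
  Wasserstein distances scale linearly with length. An extended curve does
  not have this property (its features are all local) and also produces
  near-degenerate inputs for the Delaunay triangulation.
* **Structural divergence**: Brownian motion of coordinates along the
  tree — each branch of length t adds i.i.d. Gaussian displacement of sd
  `struct_noise_sd * sqrt(t)` per coordinate to every retained residue.
  Deleted residues vanish from descendants. Inserted runs protrude as
  arcs between their flanking residues, sized so the inserted residues fit
  at ~3.8 A spacing; linear interpolation would squeeze them into a single
  inter-residue gap at unphysical density and hide indels from the
  geometry entirely.
* **Confidence**: a fraction `low_ci_fraction` of *homologous sites*
  (drawn family-wide, because disordered regions are homologous) is
  low-confidence: such residues get an index in [40, 70) and extra
  coordinate noise equal to the displacement a tripled Brownian sd would
  accumulate along the root-to-leaf path (sqrt(8) * `struct_noise_sd` *
  sqrt(depth)); everything else gets an index in [85, 99].

All randomness derives from the single config seed; equal configs give
byte-identical families.

### Default parameter choices

| parameter | default | why |
|---|---|---|
| `n_taxa` | 10 | typical small family; the hard floor is 7 |
| `seq_length` | 100 | mid-size single-domain protein |
| `birth_rate` | 2 | tree depth ~1 substitution/site, mid-range divergence |
| `sub_rate` | 1 | branch lengths are then substitutions/site |
| `indel_rate` | 0.3 | occasional indels, most pairs gapless |
| `indel_len_mean` | 3 | short indels dominate real alignments |
| `struct_noise_sd` | 0.25 A | keeps displacement below ~20% of the CA spacing over the divergence range, the regime where the distance response is quasi-linear (at 0.5 it visibly saturates) |
| `low_ci_fraction` | 0.06 | mirrors ~94% of residues having confidence >= 70 |

`simulate_family_set()` additionally draws per-family Yule rates
log-uniformly over [0.7, 7], emulating study sets whose taxa span roughly
two orders of magnitude in genetic divergence.

### What the generator does *not* emulate

No side-chain packing or rotamers, no secondary-structure rearrangement,
no covariation or site-rate heterogeneity, no correlated (domain-motion)
deformation — displacement is i.i.d. per residue; no relationship between
amino-acid identity and geometry. Consequently a green test suite shows
the *method* behaves as designed under the assumed statistical coupling,
not that real structure predictions carry this much signal.

A consequence of the Brownian design worth stating: the noise scale is
both the signal and the noise, so the rank correlation between true
distances and PH-distances is essentially invariant to `struct_noise_sd`
(saturation lowers it at large values). Coupling strength is therefore
asserted as strong positivity at two noise levels rather than as growth in
the noise parameter.

## Study conditions of the validation suite

* **Size / normalization**: ten families on one shared tree, lengths
  50–300, indels and confidence noise disabled, so protein size is the
  only varying factor. Raw Wasserstein distances correlate strongly with
  mean point count (r = 0.82 at the suite's seed); normalized ones do not
  (r = 0.08).
* **Signal recovery**: ten heterogeneous families (8–16 taxa), the refined
  protocol (confidence >= 70 plus indel masking), normalized Wasserstein
  (AC, k = 1) against true patristic distance: pooled r = 0.70 with
  within-family label-permutation p = 0.005 (199 permutations).
* **Indels**: high-indel replicates (rate 2, mean length 4): indel masking
  improves the pooled correlation in 9 of 10 replicates; unmasked
  correlations are erratic because single large indels dominate.
* **Null**: 500 within-family and 500 cross-family pairs from eight
  unrelated folds; nonhomologous distances are larger (median ratio ~4,
  one-sided rank-sum p < 1e-100).

Problem sizes (10–25 points for oracle batteries, 40–300 residues for
families, 10 families per condition) were chosen as the smallest at which
each property is statistically decided.

Pearson p-values are reported two ways: the parametric t-test (which
overstates significance because pairwise distances sharing a protein are
not independent) and a Mantel-style permutation test that relabels
proteins within families and recomputes the pooled correlation. The
permutation p is the honest one and is what the validation asserts.

## Numerical choices

* Coefficients over the field with two elements; homology in dims 1–2.
* Points are centred and inserted in seed-shuffled order before the
  incremental Delaunay triangulation (chain order is adversarial); a
  deterministic jitter of 1e-6 A puts points in general position, growing
  tenfold on the rare verification failure (the triangulation is always
  verified against the empty-circumsphere property, so a wrong
  triangulation cannot pass silently).
* VR complexes are capped at 150 points (simplex counts grow as n^4);
  larger clouds must use the alpha complex. Thresholds below the diameter
  cap unpaired classes at the threshold, with a warning.
* Bottleneck and Wasserstein are exact (no approximation parameter);
  landscapes are exact breakpoint representations with closed-form
  piecewise-quadratic integration. Zero-persistence pairs are discarded.
* Degenerate inputs: empty clouds after masking, clouds under 4 points,
  alignments with no overlapping sites, and trees without branch lengths
  all fail fast with specific errors.

## Known limitations

* At ten families, the pair-level correlation between normalized distance
  and size has fold-realization sampling noise of about ±0.2; the
  near-zero value is reproducible at the suite's fixed seeds but pooling
  hundreds of families is what makes it tight in large studies.
* Point-count normalization is calibrated for dimension-1 distances. In
  the generator, dimension-2 (cavity) distances grow faster than linearly
  with point count, so their normalized values retain a positive size
  trend; size-sensitive conclusions should rest on k = 1.
* The Wasserstein assignment is O((|P|+|Q|)^3); barcodes of ~700 intervals
  (300-residue proteins) take a few seconds per pair. Landscape distances
  on such barcodes are several times slower than Wasserstein ones.
* The homolog/nonhomolog null uses families with different random folds;
  it does not model analogous folds (structurally similar nonhomologs),
  which would narrow the separation.
* Confidence masking helps here because low-confidence sites are homologous
  by construction; on data where confidence errors are idiosyncratic per
  structure, masking can instead create pair-composition mismatch and hurt.
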