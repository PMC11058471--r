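# phsignal

Do protein 3D structures carry a phylogenetic signal, and how do you
measure it without aligning structures? `phsignal` answers this with
persistent homology: each structure becomes a 3D point cloud of its atoms,
the cloud's cycles (homological dimension k = 1) and cavities (k = 2) are
tracked across spatial scales with Vietoris–Rips or alpha-complex
filtrations, and the resulting barcodes are compared between homologs with
matching-based distances. If structures evolve with sequences, these
*PH-distances* should correlate with evolutionary distances computed from
multiple alignments (p-distances) and trees (patristic distances). The
package is for molecular evolutionists and structural bioinformaticians
who want to quantify that correlation on their own families — or study the
method itself on fully synthetic ones.

## The distances

For barcodes *P*, *Q* (multisets of (birth, death) intervals, with
diagonal augmentation for unmatched intervals):

* bottleneck: Btk(P,Q) = inf over matchings φ of max<sub>a∈P</sub> ‖a − φ(a)‖<sub>∞</sub>
* Wasserstein (q = p = 2): Ws(P,Q) = inf over matchings φ of Σ<sub>a∈P</sub> ‖a − φ(a)‖₂²
* landscape (p = 2): Ls(λ, λ′) = ( Σ<sub>ℓ</sub> ∫ |λ<sub>ℓ</sub>(t) − λ′<sub>ℓ</sub>(t)|² dt )<sup>1/2</sup>
  on the persistence landscapes λ<sub>ℓ</sub>(t)

All three are computed exactly (optimal assignment, binary-search
bottleneck, closed-form piecewise integration — no grids, no tolerances).
PH-distances are normalized by the average point count of the two compared
clouds, and two maskings remove known nuisance structure: residues with a
confidence index below 70 (AlphaFold-style pLDDT read from the PDB
B-factor column), and — per pair — residues sitting opposite an alignment
gap, so indels in one sequence do not contaminate the other structure's
cloud.

A built-in generator (`simulate_family()`) produces synthetic families
whose sequences and structures diverge together along a Yule tree, with
indels, per-residue confidence, and known true distances — every pipeline
stage is testable end to end without any external data.

## Worked example

```r
library(phsignal)

cfg <- synthetic_family_config(n_taxa = 10, seq_length = 80, seed = 42)
fam <- simulate_family(cfg)
fam
#> <family_bundle> fam1 - 10 structures, alignment 80 columns

# one structure -> point cloud -> alpha filtration -> barcodes
pc   <- extract_point_cloud(fam$structures$t01, "CA")
bars <- compute_persistence(build_alpha_complex(pc))
bars$H1
#> <barcode> k = 1 - 173 intervals
#>          birth    death
#>  [1,] 1.789825 1.845747
#>  [2,] 2.206385 2.209335
#>  ...

# all pairwise Wasserstein distances (alpha complex, k = 1), with
# confidence and pair-specific indel masking
tab <- family_ph_distances(fam, metrics = "ws", dims = 1,
                           masking = "ci+indel")
head(tab[, c("idA", "idB", "raw", "normalized", "nA", "nB", "gap_count")], 3)
#>   idA idB      raw normalized nA nB gap_count
#> 1 t01 t02 18.79447  0.2472957 76 76         0
#> 2 t01 t03 13.57933  0.1786753 76 76         0
#> 3 t01 t04 16.25180  0.2226273 73 73         3

# how well do the structural distances track the true evolutionary ones?
ev <- family_ev_distances(fam)
correlate_distances(ev$ml[cbind(tab$idA, tab$idB)], tab$normalized,
                    permutations = 199,
                    pair_ids = data.frame(family = tab$family_id,
                                          idA = tab$idA, idB = tab$idB),
                    seed = 1)
#> <correlation_result> all: r = 0.795 (n = 45, p_t = 7.21e-11, p_perm = 0.005)
```

The interval (1.79, 1.85) is a short-lived cycle appearing at squared
radius ~1.8 Å²; the 173 intervals together are the structure's k = 1
signature. `raw` is the minimal sum of squared matched costs between the
two barcodes, `normalized` divides it by the mean point count after
masking (here 76 of 80 residues survive). The Pearson r of 0.795 between
normalized Wasserstein distance and true patristic distance — with a
within-family permutation p of 0.005, the honest test given that pairs
share proteins — is the phylogenetic signal.

The `analysis/` scripts run the full study line by line: `01` simulates
the family sets, `02` shows raw distances track protein size while
normalized ones do not, `03` pools the signal across heterogeneous
families under all masking protocols, `04` quantifies what indels do and
what masking recovers, `05` contrasts homologous against nonhomologous
pairs. Each writes its tables under `results/`.

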