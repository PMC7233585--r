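# locfrust

Local frustration profiling and clustering for polymorphic protein
receptors.

Polymorphic receptors such as MHC class I molecules differ between alleles
at a modest number of positions, yet those differences reshape how well
each residue is energetically optimized for its structural environment.
`locfrust` quantifies this per position and per allele:

* **Local frustration.** On a coarse-grained structure model (one
  representative point per residue, contacts within 9.5 Å), each site is
  compared against its 19 mutational decoys (or each contact against its
  361 pair decoys) via the z-score

  *F* = (⟨*E*<sub>decoy</sub>⟩ − *E*<sub>native</sub>) / σ<sub>decoy</sub>,

  with population (1/N) variance. The single-site version is the Single
  Residue Frustration Index (SRFI): above +1 minimally frustrated, below
  −1 highly frustrated, the closed band [−1, 1] neutral. The energy model
  is a tabulated contact potential with a distance taper plus screened
  Debye–Hückel electrostatics (*k* = 4.15, *l*<sub>D</sub> = 10 Å).
* **Evolutionary importance.** Per-column information content
  *I* = Σ *p*<sub>a</sub> log₂(*p*<sub>a</sub>/*q*<sub>a</sub>) (bits,
  uniform background), and the real-value Evolutionary Trace rank
  ρ = 1 + Σₙ (1/n) Σ_g *H*_g over tree cuts into n groups (ρ = 1 for an
  invariant column).
* **Profiles and clustering.** Median SRFI per allele per position,
  SRFI change upon ligand removal (loaded median minus a single
  ligand-free structure), filtering of low-variation positions
  (≥ 0.5 SRFI variation), and agglomerative clustering of allele profiles
  with single linkage on Manhattan distances.
* **Synthetic data.** Deterministic generators for toy receptor–ligand
  complexes with a planted interface, alignments with planted group
  motifs, and SRFI matrices with planted cluster structure — every
  pipeline input with known ground truth.

It is aimed at structural bioinformaticians studying sequence–structure–
function relationships across allele panels, and at anyone needing a
tested, deterministic frustration/trace/cluster toolchain on residue-level
models.

## Worked example

```r
library(locfrust)

# toy complex: 30-residue helical receptor (chain A), 3-residue ligand
# (chain C) contacting groove positions 7-9
cx <- make_complex(groove_positions = c(7, 8, 9))
cx$model
#> structure_model: 33 residues in 2 chain(s); contacts: 56

# SRFI of the loaded complex and of the ligand-stripped receptor
loaded <- srfi_profile(cx$model, include_pair = FALSE)
free   <- srfi_profile(strip_ligand(cx$model, "C"), include_pair = FALSE)
head(loaded$per_residue, 3)
#>   chain resno aa      srfi   class
#> 1     A     1  A 1.0466606 minimal
#> 2     A     2  A 1.0466606 minimal
#> 3     A     3  A 1.0075900 minimal

# binding delta: positive exactly at the ligand-contacting positions
d <- delta_srfi(median_srfi(list(loaded), chain = "A"), free, chain = "A")
round(d[5:10], 4)
#>      5      6      7      8      9     10
#> 0.0000 0.0000 0.1954 0.1954 0.1954 0.0000

# planted 3-group allele panel: filter to informative positions, cluster
sm   <- make_srfi_matrix(seed = 7)          # 90 alleles x 60 positions
kept <- variation_filter(sm$matrix, 0.5)    # the 14 planted positions
cl   <- cluster_profiles(sm$matrix, k = 3, positions = kept)
table(cl$assignment, sm$groups[names(cl$assignment)])
#>      1  2  3
#>   1 30  0  0
#>   2  0 30  0
#>   3  0  0 30

# screening length from solution conditions
debye_length(298.15, 80, 0.1)
#> [1] 9.711304   # rounds to the conventional 10 A
```

The delta of +0.195 at positions 7–9 (and exactly zero elsewhere) shows
the ligand contact is stabilizing and strictly local; the 14 recovered
positions and the diagonal confusion table show the variation filter and
single-linkage clustering recover the planted allele groups perfectly.

The full pipeline — complex, profiles, delta, matrix, filter, clustering,
trace, with a checksummed manifest — runs with:

```r
run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

A thin command-line front end with `frustrate` / `trace` / `cluster` /
`simulate` / `run` subcommands ships in `inst/scripts/locfrust.R`.

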