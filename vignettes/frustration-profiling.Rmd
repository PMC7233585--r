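---
title: "Local frustration profiling of polymorphic receptors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local frustration profiling of polymorphic receptors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locfrust)
```

## The problem

Highly polymorphic receptors such as MHC class I molecules present short
peptide ligands in a binding groove whose residues vary between alleles.
Two complementary per-position descriptions help explain which positions
matter: an *evolutionary* one (how conserved a position is, and where in the
allele phylogeny variation arises) and an *energetic* one (how well the
residue occupying a position is optimized for its structural environment —
its local frustration). `locfrust` computes both on residue-level structure
models and alignments, aggregates frustration into per-allele profiles,
quantifies the change upon ligand removal, and clusters alleles by their
frustration profiles.

## The energy model

Structures are coarse-grained to one representative point per residue (the
beta-carbon; alpha-carbon for glycine). Two residues are *in contact* when
their representative points lie within 9.5 Å, excluding same-chain pairs
closer than 3 in sequence; inter-chain pairs are never excluded by sequence
separation. The total energy is a sum over contacts of two terms:

* a **tabulated contact term** `M[a_i, a_j] · w(r_ij)`, where `M` is a
  symmetric 20×20 pair potential and `w` a linear switching function with
  full weight up to 6.5 Å and zero from 9.5 Å. The shipped default `M` is a
  hydrophobicity-based potential built from Kyte–Doolittle hydropathy `h`:
  `M[a,b] = −h_a h_b / s² + γ ((h_a − h_b)/s)²` with `s = 4.5`, `γ = 0.5`.
  The product term rewards hydrophobic burial and the mismatch term
  penalizes pairing residues of very different hydropathy. The mismatch
  term is essential: a pure product potential is *separable*, making every
  single-site decoy energy a linear function of the mutant's hydropathy and
  collapsing the z-score to a function of the sign of the summed partner
  hydropathy. Every downstream computation is agnostic to the matrix
  choice — any symmetric 20×20 table can be supplied.
* a **screened electrostatic term** (Debye–Hückel),
  `V = k q_i q_j exp(−r_ij / l_D) / r_ij`, over the same contact pairs,
  with formal charges −1 (D, E), +1 (K, R) and 0 otherwise. Defaults are
  `k = 4.15` (aqueous solution; treated as an opaque multiplier since the
  index below is scale-free) and `l_D = 10` Å. `debye_length()` reproduces
  the derivation of `l_D` from solution conditions: at 25 °C, relative
  dielectric 80 and ionic strength 0.1 M the closed form gives ≈ 9.7 Å,
  conventionally rounded to 10 Å. Restricting the electrostatic term to the
  contact cutoff keeps decoy enumeration local; the term decays to ~7% of
  its bare-Coulomb value at the cutoff already.

Energies are in arbitrary units throughout; frustration indices are
z-scores, so only relative energies matter (and indeed the index is
invariant under any positive affine rescaling of the whole energy model, a
property the test suite enforces to 1e−9).

## Mutational frustration indices

For a site (or a contact pair), decoys are generated by substituting the
amino-acid identity — and its derived charge — with every alternative,
keeping coordinates and contact topology fixed: 19 decoys for one site, 361
for a pair. Decoy energies are full-model totals with the terms touching
the mutated residue(s) recomputed; this incremental bookkeeping is checked
against exhaustive per-mutant recomputation in the tests. The index is

F = (⟨E_decoy⟩ − E_native) / σ_decoy,

with the *population* (1/N) standard deviation. The orientation is
decoy-minus-native: a native identity more stable than its alternatives
scores positive. The single-site version is the Single Residue Frustration
Index (SRFI). Values above +1 are classified *minimally frustrated*, below
−1 *highly frustrated*, and the closed band [−1, 1] *neutral*. Full decoy
enumeration replaces random decoy sampling: at 19 and 361 decoys per site
the exhaustive ensemble is cheap, removes all seed dependence, and makes
profiles byte-reproducible. Sites with no contacts (or identical decoy
energies) have an undefined index; they are reported as `NA`, never as a
number, and a warning names the site.

## Evolutionary descriptors

Per-column conservation is Shannon information content
`I = Σ_a p_a log2(p_a / q_a)` in bits, with empirical non-gap frequencies
`p` and a uniform background `q = 1/20` (so a conserved column scores
log2 20 ≈ 4.32 bits). The real-value Evolutionary Trace rank is

ρ = 1 + Σ_{n=1}^{N−1} (1/n) Σ_{g=1}^{n} H_g,

where cutting the sequence tree into n groups defines the groups g, and
H_g is the Shannon entropy (natural log) of the column within group g.
An invariant column scores exactly 1; variation confined to deep splits is
penalized less than variation inside recent groups. The group term is
entropy rather than background-weighted information: weighting by a 1/20
background inside the sum would drive conserved columns negative and break
the rank's anchoring at 1, so the entropy form is used. Because no tree
construction method is prescribed for this rank, the package builds a
deterministic average-linkage tree on normalized Hamming distances (rows
sorted by label first, so the result is independent of input order); an
externally built tree (`hclust` or an ultrametric `phylo`) can be supplied
instead.

## Profiles, deltas and clustering

With several ligand-loaded structures per allele, the per-position
**median** SRFI forms the allele's profile (medians over the available
values; an even count averages the central pair). The **binding delta** is
the loaded median minus the SRFI of a single ligand-free structure obtained
by simply deleting the ligand chain; positive values mean binding reduces
frustration. Because a residue's SRFI depends only on its own contacts,
deletion perturbs exactly the ligand-contacting residues — a locality the
acceptance checks exploit.

Allele profiles are assembled into an SRFI matrix (serialized with
positions as rows). Positions whose SRFI varies too little across alleles
carry no grouping signal and are excluded before clustering. The filter
keeps positions with at least 0.5 SRFI variation; *variation* here is the
standard deviation across alleles, because the sd of a noise-only position
is independent of how many alleles are profiled, so a fixed 0.5 cutoff
means the same thing for 12 alleles as for 1400. The range (max − min) —
an alternative reading, selectable via `measure = "range"` — grows with the
allele count (the expected range of n Gaussian noise values is σ·d_n, with
d_n ≈ 3–5 for panels of 10–100), which would make the cutoff panel-size
dependent and, at realistic noise levels, keep every position. Variance is
also selectable.

Clustering is agglomerative with **single linkage** on **Manhattan
distances** between profiles; allele labels are sorted before
agglomeration for deterministic tie-breaking, and positions with missing
values in any clustered allele are dropped (with a warning) beforehand.
Cluster extraction cuts the dendrogram at an explicit k — the package does
not guess a cluster count. Subset analyses (e.g. clustering on binding
pocket positions only) are the same operations applied to a position
subset.

## The synthetic-data generators

Real inputs for this analysis are allele sequence databases, homology
models and ligand-affinity predictions; those stages are out of the
package's scope. The generators instead produce every input shape with
known ground truth:

* `make_complex()` — a helix-like receptor (radius 2.3 Å, 2.2 Å rise, 100°
  twist per residue, giving same-chain contacts at sequence offsets 3–4
  under the default cutoff) plus a ligand chain placed radially 7.5 Å
  outside designated groove positions, so each ligand residue contacts
  exactly its groove position. The default sequences (alanine background,
  isoleucine at the groove and on the ligand) make the groove contact
  stabilizing, so ligand removal lowers SRFI there. The realized contact
  map is verified against the request; an unsatisfiable geometry errors.
  The geometry is a toy: it reproduces interface locality, not receptor
  anatomy.
* `make_msa()` — alignments with fully conserved columns, group-specific
  motif columns (emulating lineage motifs at a handful of groove
  positions), and uniform-random columns; defaults are 3 groups of 10
  sequences, 30 columns.
* `make_srfi_matrix()` — group mean offsets (−2, 0, +2) at 14 signal
  positions out of 60, Gaussian noise (sd 0.3) everywhere, 30 alleles per
  group. The offsets dwarf both the noise and the 0.5 filter threshold, so
  filtering and 3-cluster extraction recover the planted structure exactly.

All generators are pure functions of their arguments including the seed:
they restore the caller's RNG state and produce byte-identical text across
runs. Problem sizes (30-residue receptor, 90-allele matrices, 30-sequence
alignments) were chosen so a full pipeline run completes in seconds while
still exercising every code path; they are deliberately far below the
scale of a real allele panel.

What passing these fixtures does *not* show: realism of the geometry or
potential, behaviour under conformational change upon binding (the
ligand-free structure is a rigid deletion), alignment columns with
covariation, or cluster structure that is not well-separated. Conclusions
about real receptor panels require real structures and alignments fed
through the same interfaces.

## Numerical choices and limitations

* Contact distances at exactly the cutoff count as contacts; classification
  band bounds are inclusive to neutral.
* Zero-variance decoy ensembles yield `NA` (propagated, never silently
  dropped); medians and filters skip `NA`s, and positions missing in more
  than half the alleles are dropped with a warning.
* The altloc policy keeps the first variant; insertion codes are rejected
  (the intended inputs, homology models, have none).
* Pair indices cost 361 energy evaluations per contact; for large
  structures compute them only when needed (`include_pair = FALSE`).
* The pipeline writes numbers with `%.10g`, which makes outputs
  byte-stable across runs and platforms using IEEE doubles.
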