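---
title: "Methods: from compound library to ranked hits, degrons and proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from compound library to ranked hits, degrons and proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pocketscreen)
```

## What the package models

`pocketscreen` is a desk-scale implementation of a structure-guided virtual
screening pipeline of the kind used to find small-molecule inhibitors of a
deubiquitinase (the motivating system is the OTU-family enzyme OTUD7A, whose
catalytic activity stabilizes the EWS–FLI1 fusion oncoprotein in Ewing
sarcoma), together with the two analyses that surround such a campaign
biologically: scanning substrate sequences for the SPOP-binding degron that
routes the substrate to degradation, and post-processing a TMT proteomics
experiment that measures what happens when the deubiquitinase is depleted.

The pipeline stages, and the modelling conventions adopted at each one, are
described below in the order data flows through them.

## Library standardization and filtering

Raw vendor libraries arrive as SMILES with salts, isotope labels, charged
species and inconsistent aromatic/Kekulé forms. `standardize_molecules()`
keeps the largest organic fragment, clears isotope labels, neutralizes
charges where a plain protonation change suffices (zwitterions stay neutral
overall), and emits one canonical form per molecule, so the operation is
idempotent. Parsing and canonicalization are delegated to OpenBabel
(via ChemmineOB); the package's own logic is the fragment choice and the
standardization contract.

`compute_descriptors()` then derives the triage descriptors on the package's
own connection-table representation:

* molecular weight (implicit hydrogens included);
* total atom count — hydrogens are counted, the stricter reading of "total
  atoms", and this is configurable (`count_hydrogens = FALSE`);
* rotatable bonds — non-ring single bonds between two heavy atoms that each
  have at least one further heavy neighbour, excluding amide C–N;
* stereocenters — atoms with four distinct substituents, decided by
  canonical branch signatures, so both assigned and unassigned centers
  count.

`filter_config()` encodes the screening-library windows: MW in [100, 700] Da
inclusive, at most 6 stereocenters, 60 atoms, 15 rotatable bonds, and the
element whitelist C, N, S, H, O, P, B plus halogens (F, Cl, Br, I;
astatine is excluded as in any drug-like library). All bounds are
inclusive — a molecule exactly at every bound passes. Substructure triage
(PAINS, toxicophores, medicinal-chemistry rules) is SMARTS-driven; because
the vendor rule sets are not public, the package ships small, documented
subsets written from the published pattern families, and every set is
replaceable through `filter_config(rulesets = ...)`. A malformed SMARTS
fails at configuration time, never per molecule.

## Binding-site definition

`flood_fill_site()` grows the pocket from a seed point on an absolute
1 Å lattice: a voxel is a wall when a heavy atom lies strictly closer than
`r_occ` (default 2 Å) to its center, growth is 6-connected, and the region
is truncated at `max_radius` (default 12 Å) from the seed voxel. The
published description of this step names only "a flooding algorithm based
on an initial seed"; connectivity, occupancy radius and truncation are this
package's choices and are all configurable. The lattice is absolute
(cells `[i, i+1)` Å), so any seed inside the same voxel produces the same
site, and the reported voxel offsets are anchored at the seed voxel.

`site_from_residues()` supports the second way such screens are seeded: a
residue list (for the motivating target, the 24 residues lining the S1
distal ubiquitin-binding pocket, available as `otud7a_s1_residues()`).
The seed is the nearest unoccupied voxel to the residues' centroid.

## Pose ensembles

`generate_poses()` places a rigid conformer: rotations uniform on SO(3)
(Shoemake quaternions), translations uniform over flooded-voxel centers,
rejection on a heavy-atom clash criterion (default 2.2 Å). The ensemble
size defaults to 64, the screening convention. No torsional search is
performed — the original screen does not document a docking engine, and
rigid placement of a supplied conformer is the minimal model consistent
with "an ensemble of poses". Acceptance below one pose per 10,000 attempts
is treated as an unusable pocket.

## Featurization

`rasterize()` maps a site-centered complex into a binary occupancy tensor:
by default 30×30×30 voxels at 1 Å, spanning [−15, +15) Å, with 16 channels
crossing entity (protein/ligand) with eight element classes (C, N, O, S, P,
B, halogen, other). The published architecture fixes only the grid (30³,
1 Å) and that grid values encode "the presence of different atom types";
the channel vocabulary is this package's choice and is configurable
(`channel_scheme()`), including a minimal 2-channel protein/ligand scheme
used for desk-scale training sets. Occupancy is binary presence; voxels are
half-open cubes, atoms outside the grid are ignored, and an empty frame is
a zero tensor, not an error. `augment_frame()` applies the
anti-memorization augmentation: one uniform rotation about the site center
plus a translation uniform in [−2, 2]³ Å (the translation range is
unstated in the source description; 2 Å keeps complexes inside the default
grid margin). For complexes in generic position (no two same-channel atoms
within one voxel diagonal, all atoms strictly inside the grid) per-channel
occupancy counts are exactly conserved under augmentation; lattice-aligned
toy structures can merge atoms into one voxel, which is why the
conservation tests use generic-position fixtures.

## The scorer

`network_config()` reproduces the published affinity-scoring architecture:
five valid-padded 3D convolutions of 32×3³, 64×3³, 64×3³, 64×3³, 64×2³
filters, each followed by a rectified-linear unit, then a fully connected
layer of 256 ReLU units and a scalar output on the pKi/pIC50 scale
(−log10 molar affinity). Strides are not published; the default
(1, 2, 2, 2, 1) collapses a 30³ input to 1³ ahead of the dense head and
trains on one CPU. The layer stack is validated (spatial extent below one
voxel is a configuration error) and the parameter count is a closed-form
function of the configuration.

Pose scores are combined by Boltzmann-weighted averaging. The published
description names the operation but not its form; the package adopts the
softmax-weighted mean

$$\mathrm{agg}(s; \beta) = \frac{\sum_i s_i e^{\beta s_i}}{\sum_i e^{\beta s_i}},$$

computed with a max-shift for overflow safety. β = 0 is the arithmetic
mean, β → ∞ the maximum; the default β = 1 sits between them and is
configurable. Aggregation is applied inside the training loss (it is
differentiable), since the ensemble is scored "to produce a final score"
that is compared against one measured affinity.

`train_scoring_model()` minimizes mean squared error with Adam over seeded,
shuffled minibatches of 64 complexes — the published training contract
(MSE, adaptive moments, minibatch 64). Learning rate (default 1e-3),
epochs and the train/test split are not published and are exposed in the
training interface. Training is bit-reproducible for a fixed seed under
single-threaded numerics. The convolutions are implemented as batched
im2col gathers with cached sparse scatter matrices; gradients were verified
against finite differences.

## Ranking and diversity selection

`score_library()` runs pose generation → featurization → prediction per
compound, deriving per-compound randomness from the compound id so the
ranking is invariant to library order; ties in score break
lexicographically. `top_k()` keeps the examination window (default 5000)
and `pick_diverse()` performs greedy MaxMin selection on Tanimoto distances
over 2048-bit radius-2 circular fingerprints, initialized at the top-ranked
candidate, default 89 picks. The original 5000 → 89 triage was partly
manual ("diverse chemical scaffolds"); MaxMin is the standard automatic
surrogate. Each greedy step is exactly the exhaustive argmax of the minimum
distance to the selected set (ties by id) — the property the tests verify
against brute force; no claim is made that the greedy *set* is the global
max-min optimum, which greedy selection does not guarantee in general.

## Degron scanning

`scan_spop_degrons()` scans every overlapping 5-mer against the SPOP degron
consensus nonpolar–polar–S–S/T–S/T. The motivating instance is the VTSSS
degron between the ETS DNA-binding domain and the C-terminus of the FLI1
segment retained in EWS–FLI1; the serine-to-alanine triple mutant
(S464A/S465A/S466A) ablates the match, which `mutate_and_rescan()` models
directly. The consensus position classes are conveyed in the source only
by an alignment with canonical SPOP substrates, so the defaults
(Φ = {A,V,L,I,M,F,P,G,W,Y,C}; π = {S,T,N,Q,D,E,H,K,R,Y,C}) follow the
SPOP-degron literature and every class is configurable. Coordinates are
1-based; `X` never matches.

## TMT post-processing

`normalize_channels()` implements the equal-loading normalization: each
reporter channel is summed across quantified proteins and scaled to the
mean channel sum. `differential_abundance()` computes
log2(+Tet/−Tet) fold changes on intensities and two-sided Welch t-tests on
log2 intensities (the upstream software is named in the source but not the
test; Welch is the defensible default, pooled variance is available).
`apply_thresholds()` applies the published cuts — p < 0.05, |log2FC| ≥ 0.5 —
with an inclusive fold-change boundary, because the packaged downregulated
table contains an entry at exactly −0.5. P-values are deliberately
uncorrected, matching the published threshold; FDR adjustment can be
applied upstream via `p.adjust`. Proteins with a zero group mean or no
within-group variance are flagged and excluded from calling. The packaged
tables use the sign convention negative = lower upon depletion, which
follows the biology described in the source text; the source table header
nominally reads the other way around, a discrepancy recorded here rather
than resolved. `overlap_with_targets()` intersects calls with a target
gene list and classifies agreement with a second study's calls into groups
I (up/up), II (down/up), III (up/down) and IV (down/down); the groups
partition the common significant set.

## Synthetic data: what it emulates and what it does not

Because no raw screening corpus or proteomics archive is redistributable,
every stage is exercised on seeded generators whose truth is known by
construction:

* `make_pocket()` builds hollow cubic shells with a cavity and a capped
  mouth channel on a voxel-aligned lattice. Occupancy is strict
  (distance < `r_occ`), so the cavity voxel count has the closed form
  `(shell_edge − 4)³ + 2`; atom jitter is tangential to each face (and the
  mouth surround stays exact) so seeds vary coordinates, never topology.
* `make_ligand_library()` assembles molecules from a fragment grammar whose
  products provably satisfy every filter, then plants exact numbers of
  single-rule violators, salts and isotope forms. Filter tests are equality
  checks against this truth, not approximations.
* `oracle_affinity()` is a deliberately simple contact-count oracle:
  pK = a0 + a1·contacts − a2·clashes + noise (defaults 4, 0.3, 0.5;
  contact cutoff 4 Å; noise 0.2 pK). With ligands of 4–10 heavy atoms this
  spreads labels over roughly 1–3 pK against 0.2 pK of noise — the
  signal-to-noise regime of real affinity collections, which span several
  log units — so scorer recovery is a meaningful parameter-recovery
  experiment rather than a fit to noise. Its purpose is mechanism testing;
  it has no physical realism (no chemistry-dependent interactions, no
  torsions, no desolvation).
* `make_screen_dataset()` chains the generators into labelled pose-grid
  ensembles with a by-compound train/test split (no pose leakage). Pocket
  shells are sized so the whole complex — mouth cap included — fits the
  grid: the network must be able to see every atom the oracle counts, and
  the generator asserts this. The desk-scale recovery experiment uses 500
  complexes (400 train / 100 test), 16³ two-channel grids and 8 poses per
  complex — sizes chosen so the whole experiment trains in minutes on one
  CPU; the screening-facing defaults (30³, 16 channels, 64 poses) remain
  the package defaults.
* `make_tmt_fixture()` draws log-normal 10-plex intensities (3 −Tet,
  3 +Tet, 4 unassigned channels) with channel loading factors and planted
  log2 effects. The headline recovery setting plants 50 of 1000 proteins
  at log2FC −1 with 0.1 within-group SD, where the Welch test at n = 3 has
  essentially full power and the null p-values are uniform.

Passing on these fixtures demonstrates that each mechanism is implemented
correctly — flood fill equals brute-force reachability, filters recover
planted truth exactly, the scorer recovers a known label-generating
function, the thresholds find planted effects at the expected rates. It
does not demonstrate performance on real vendor libraries, real pockets or
real proteomes, whose structure (tautomers, flexible ligands, correlated
intensities, missing values) the generators intentionally do not model.

## Numerical choices and degenerate inputs

* Occupancy and clash tests use strict inequalities; threshold equalities
  are therefore stable for lattice-aligned fixtures.
* The flood-fill truncation ball is inclusive (`≤ max_radius`), so
  `max_radius = 0` floods exactly the seed voxel.
* `boltzmann_aggregate()` max-shifts before exponentiation; β may be 0 but
  not negative or infinite.
* Ranking ties break lexicographically by compound id everywhere a
  selection is made, making every ranked artifact deterministic.
* Proteins with zero group means are excluded from calling rather than
  imputed; imputation is out of scope.
* Empty structures, buried seeds, unusable pockets, mismatched grid specs
  and divergent training all raise typed conditions
  (`seed_buried`, `pocket_too_small`, `grid_spec_mismatch`, `diverged`).

## Known limitations

* Rigid-body poses only; no torsional sampling or receptor flexibility.
* Binary occupancy features; no partial charges or electrostatics.
* The shipped substructure rule sets are small stand-ins for the vendor
  PAINS/toxicophore/medchem collections.
* Grid tensors are kept in memory (or written to plain-text formats);
  no HDF5 container is used in this implementation.
* The scorer is trained per experiment; no pretrained global weights are
  shipped or claimed.
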