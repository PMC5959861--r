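---
title: "Methods: analysing receptor-nanotube adsorption trajectories with cntmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing receptor-nanotube adsorption trajectories with cntmd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntmd)
```

`cntmd` post-processes molecular-dynamics trajectories of membrane
receptors — olfactory receptors and their structural surrogates in
particular — adsorbing onto single-walled carbon nanotubes. This
vignette explains the models and procedures the package implements,
the parameters that matter, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was
genuinely open.

## Data model and conventions

A `mol_system` is an ordered atom table (name, element, residue,
chain, group label, radius, partial charge, Lennard-Jones ε/σ) with an
optional box; a `mol_trajectory` adds an `n_atoms × 3 × n_frames`
coordinate array with strictly increasing times. Units are Å, ps, e
and kcal/mol everywhere; atom and residue indices are 1-based
throughout, matching R convention and the PDB's own numbering. Group
labels (`receptor`, `tube`, `solvent`, `ligand`, `other`) are inferred
from residue names at read time — the tube is a pseudo-residue `CNT`
of uncharged Lennard-Jones carbons — and drive the selection language
(`group:tube`, `backbone`, `heavy`, `resid:5-10`, combined with
`and`/`or`/`not`).

PDB fixed columns carry three coordinate decimals, so PDB round trips
are exact to 5×10⁻⁴ Å — a property of the format, not the reader. The
XYZ writer emits six decimals and round-trips below 10⁻⁴ Å.

## Adsorption metrics

An atom counts as adsorbed when its minimum distance to any tube atom
is **at most 6 Å**, the conventional hydrophobic-interaction range. The
boundary is inclusive ("within 6 Å"); only receptor heavy atoms are
counted, while every tube atom is a potential contact. Counting uses a
cell list with cell size equal to the cutoff; an all-pairs brute force
is kept in the test suite as the oracle. A residue is adsorbed when any
of its heavy atoms is.

The buried receptor-tube interface is the contact area

> contact area = ½ [(SAS_rec + SAS_cnt) − SAS_complex],

with the three solvent-accessible surface areas computed on the
isolated receptor, the isolated tube, and their union. SASA uses the
Shrake-Rupley method with a **deterministic golden-section spiral** of
960 points per atom and a 1.4 Å water probe. A deterministic point set
makes every result bit-reproducible; the price is that the point set is
not mirror-symmetric, so exactly symmetric fixtures agree to the
point-set resolution (~0.5% at 960 points) rather than bit-for-bit.
Sample points falling exactly on a neighbouring sphere's surface are
ceded to the lower-indexed atom, so coincident equal spheres expose
exactly one sphere's worth of area. Whether the contact area should use
the same probe radius as the nonpolar-solvation SASA is not fixed
anywhere; both default to 1.4 Å and are independently configurable.

RMSD series superpose each frame on a reference (crystal or initial
structure; the choice is configuration, not a constant) over a fit
selection, then measure over a possibly different selection — e.g. fit
on the whole receptor backbone, measure on the pocket backbone, which
is how pocket drift inside a globally fitted receptor is isolated.
Superposition is the Kabsch SVD solution with the determinant sign
correction, requiring ≥3 non-collinear fit atoms.

## DCCM and the protein structure network

The dynamical cross-correlation matrix is

> C(i,j) = c(i,j) / [c(i,i) c(j,j)]^½,  c(i,j) = ⟨Δr_i · Δr_j⟩,

over Cα displacements from the mean structure. The mean is found by an
iterated fit — superpose on the current mean, recompute, repeat until
the mean shifts by <10⁻⁶ Å or 10 iterations — so the result does not
depend on an arbitrary reference frame. Residues with zero positional
variance are an error by default (`zero_variance = "drop"` removes
them).

The structure network takes residues (Cα-bearing) as nodes and weighs
residue pairs by

> I_ij = n_ij / √(N_i N_j) × 100,

where n_ij counts distinct side-chain heavy-atom pairs within
**4.5 Å** and N_i is a per-residue-type normalization. Design choices,
each configurable:

* side chains are heavy atoms excluding N, CA, C, O (and OXT); glycine
  contributes its CA as a one-atom pseudo-side-chain so it does not
  vanish from the network;
* sequence neighbours (|i−j| ≤ 1) are excluded as covalently coupled,
  the standard PSN practice;
* the normalization table shipped in
  `inst/extdata/psn_normalization.tsv` holds the standard published
  per-residue-type constants, with default 100 for unknown types;
* the edge cutoff `Imin` defaults to 3.0 on the percent-like I_ij
  scale, and summary networks keep edges present in at least half the
  frames (`occupancy_min = 0.5`). Published PSN analyses rarely state
  these two values; both are explicit parameters here, echoed into
  every run manifest.

Pathways between adsorbed residues (sources) and pocket residues
(sinks) are **minimal-hop** paths through network edges whose endpoint
residues also move in a correlated way, |C| ≥ `corr_min` (default
0.3). Among equal-hop paths the larger total edge strength wins, then
lexicographic node order — fully deterministic. A path's frequency is
the percentage of frames in which *every* consecutive pair clears
`Imin` in that frame's network; per-frame networks give frequencies,
the windowed occupancy network gives one summary topology. Top
starting/ending nodes are counted weighted by path frequency.

## The energy ledger

Binding energetics follow the single-trajectory MM-PBSA scheme:
receptor and tube/odorant coordinates are extracted from complex
frames, so the internal term cancels identically and

> ΔE_gas = ΔE_ele + ΔE_vdw,  ΔG_solv = ΔG_npsolv + ΔG_psolv,
> ΔG_binding = ΔE_gas + ΔG_solv,

with no conformational-entropy term — the package computes relative
affinities, not absolute free energies. Gas-phase terms are all-pairs
sums (no cutoff; a simulation engine's real-space cutoff is a
simulation concern, not a rescoring one): Coulomb with
k = 332.0637 kcal Å mol⁻¹ e⁻², Lennard-Jones 4ε[(σ/r)¹²−(σ/r)⁶] with
Lorentz-Berthelot combining. Nonpolar solvation is γ·SASA with
γ = 0.0072 kcal mol⁻¹ Å⁻²; its Δ is the complex-minus-parts SASA
change.

Polar solvation is a pluggable contract (deterministic per frame,
additive): `"zero"`, a user function, or the built-in Born-style
screening model with interior/exterior dielectrics 1/80 — self terms
−½(1/ε_in − 1/ε_out) k q_i²/(R_i + probe) plus screened cross terms
with effective radius f_ij = √(r_ij² + B_i B_j). A finite-difference
Poisson-Boltzmann solver is out of scope by design, so the package
does **not** claim quantitative agreement with grid-PB polar values;
the Born model keeps the ledger complete and exactly additive. For
printed component tables the package checks the footnote identities
and *flags* inconsistent rows rather than fixing them (the shipped
copy of the published odorant tables contains one internally
inconsistent binding row, which the checker reports).

Standard errors use 5-block averaging over the analysis window. The
per-residue decomposition gives each receptor residue its full
pairwise gas terms with the ligand, the nonpolar delta of its own
atoms plus the ligand's burial apportioned by the residue's share of
the receptor-side SASA change, and its full screened cross terms —
making the profile sum *exactly* to the ledger totals, which the tests
assert to 10⁻⁶.

## Pocket volume and hydration

No standard algorithm is attached to published GPCR pocket volumes, so
the package defines one and documents it: grid points inside the
padded convex hull of the pocket-lining heavy atoms that a 1.4 Å probe
can occupy (≥ atom radius + probe from every receptor atom), counted
at 0.5 Å spacing with voxel-centre sampling so the counted volume
tiles space exactly. The hull is computed from support argmaxes over
1024 golden-spiral directions: when few candidate vertices remain
(polytope-like linings) exact facets are enumerated from point
triples; otherwise the directional supporting half-spaces serve as a
tight outer approximation (the right regime for smooth, shell-like
linings, where it is accurate to well under 1%). Padding offsets the
facet planes outward without rounding edges. This estimator is
deterministic and validated against an analytic 5 Å spherical cavity
(within 5%); it is *not* guaranteed to reproduce volumes from other
tools, which differ by construction.

Water structure uses oxygen positions only. The density grid defaults
to 0.5 Å voxels over a 150 Å box; frames are rms-fitted to a reference
over all receptor atoms first, and waters falling outside the box are
tallied separately so that in-box + out-of-box counts equal
n_waters × n_frames exactly. Grids are written in OpenDX scalar-field
format. The axial profile is the mean per-frame water count per Z bin;
Z is taken as the membrane normal of the input frames, with no axis
auto-detection.

## Screening statistics

Docking scores are oriented **more negative = stronger**; the
orientation is recorded in run manifests. The top-one-third subset
ranks by a descriptor and keeps ⌊n/3⌋ records (44 of 132), ties broken
by id. ROC positives are always a caller-supplied id set — the package
does not invent activity labels — and the AUC is the tie-aware
Mann-Whitney probability that a random positive outranks a random
negative, which the tests pin to an all-pairs counting oracle at
10⁻¹². Score-descriptor trends use equal-count bins plus the Spearman
rank correlation (0 by convention for constant scores).
Class-selectivity comparisons run two-sided Wilcoxon rank-sum tests on
every class pair (exact where the implementation allows) with
Benjamini-Hochberg adjustment at 0.05; singleton classes are excluded
with a warning.

## Synthetic data and what passing tests show

Each generator draws from one explicitly seeded stream, restores the
global RNG state, and emits a ground-truth block sufficient to compute
every downstream expected value:

* `gen_correlated_trajectory` — Gaussian Cα fluctuations with a
  specified correlation (blocks or exponential decay), i.i.d. over x,
  y, z. The rigid-body component of every frame is removed at
  generation time and the **projected** correlation matrix is emitted
  as truth, because any DCCM calculation superposes frames before
  correlating: without the projection the estimable quantity would
  differ from the input matrix, markedly so for short chains. At the
  scale used for validation (10 residues, 5000 frames) the package
  recovers the truth to <0.05.
* `gen_adsorption_trajectory` — a rigid, coarse four-helix bundle (CA
  plus a CB pseudo-side-chain per residue) held at programmed
  separations from a cylindrical carbon lattice, with optional seeded
  jitter; true per-frame adsorbed counts come from an all-pairs brute
  force at generation time. Realism is not the goal — countability is.
* `gen_water_box` — water oxygens drawn per frame from a programmed
  piecewise axial density.
* `gen_toy_complex` — a fully parameterized two-group system with
  brute-force reference energies.
* `gen_odor_table` — 132 records with descriptors uniform over
  MW 42-236 g/mol, volume 45-267 Å³, logP 0.7-9.6 (the ranges of the
  motivating odorant set), and scores from a monotone or
  turnover-at-170 Å³ response plus Gaussian noise (0.5 kcal/mol
  default).

These generators emulate the *statistical structure* the analyses
consume — programmed covariances, plateaus, densities, responses —
not the physics that produces it in real systems: no force field, no
membrane, no solvent structure, no docking. A passing suite therefore
certifies that the estimators recover known ground truth under their
stated assumptions and match independent oracles (brute force, BFS,
analytic geometry, `bio3d`, `igraph`), not that any particular real
receptor behaves as the synthetic systems do. Headline figures from
microsecond membrane simulations (absolute RMSD levels, pathway
counts, PB solvation values, absolute pocket volumes) are
method- and trajectory-dependent and are deliberately not targets.

## Problem sizes and numerical notes

The shipped validation uses sizes a laptop handles in seconds: SASA
fixtures of tens of atoms at 960 points, a 10-residue/5000-frame
correlation recovery, 100 random path-search graphs of ≤20 nodes, a
60-atom staged-adsorption bundle over 30 frames, 250-water boxes over
8 frames, and an 800-atom spherical shell for the pocket estimator.
All thresholds, cutoffs and seeds live in one place
(`default_config()`) and every stage echoes its full configuration,
input hashes and seed into `manifest.json`, so a manifest suffices to
reproduce any run bit-for-bit. Degenerate inputs fail loudly and
early: empty selections, <3 or collinear fit atoms, coincident charged
atoms, non-PSD correlation specifications, coplanar pocket linings,
overlapping schedule windows, inconsistent PDB models.
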