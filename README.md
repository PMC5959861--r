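# cntmd

Post-analysis toolkit for molecular-dynamics trajectories of membrane
receptors adsorbing onto single-walled carbon nanotubes (CNTs).

Immobilizing an olfactory receptor on a carbon nanotube is a standard
route to bioelectronic noses, but the adsorption perturbs the receptor:
it reshapes the odorant-binding pocket, rewires internal communication
between the adsorbed intracellular face and the pocket, and shifts the
receptor's selectivity across odorants. `cntmd` implements the
quantitative post-processing such a study needs, end to end, for anyone
analysing receptor-nanomaterial MD trajectories:

* **Adsorption geometry** — Kabsch superposition and RMSD series;
  Shrake-Rupley solvent-accessible surface area (SASA); the buried
  interface ("contact area")
  `½[(SAS_rec + SAS_cnt) − SAS_complex]`; counts of receptor heavy atoms
  and residues within the 6 Å hydrophobic-contact criterion of the tube
  surface.
* **Correlated dynamics and allosteric pathways** — the dynamical
  cross-correlation matrix (DCCM)
  `C(i,j) = c(i,j) / √(c(i,i) c(j,j))` of Cα fluctuations about the
  iterated mean structure; a protein structure network (PSN) with edge
  weights `I_ij = n_ij / √(N_i N_j) × 100` from side-chain heavy-atom
  contacts at 4.5 Å; minimal-hop communication pathways between adsorbed
  and pocket residues, filtered by correlated motion, with per-frame
  path frequencies and top starting/ending node summaries.
* **Energetics** — a single-trajectory MM-PBSA-style ledger
  `ΔG_bind = ΔE_ele + ΔE_vdw + ΔG_npsolv + ΔG_psolv` with all-pairs
  Coulomb and Lennard-Jones terms, `ΔG_npsolv = γ·ΔSASA`
  (γ = 0.0072 kcal mol⁻¹ Å⁻²), a pluggable polar-solvation model
  (Born-style screening built in; dielectrics 1/80), block-averaged
  standard errors, exact per-residue decomposition, and consistency
  checks for printed component tables.
* **Pocket and hydration geometry** — pocket backbone RMSD inside a
  globally fitted receptor; grid-based cavity volume within the padded
  convex hull of pocket-lining atoms; water-oxygen density grids
  (OpenDX output) and axial hydration profiles after rms fitting.
* **Screening statistics** — odorant score tables with molecular
  descriptors (MW, volume, logP, chemical class); top-one-third subset
  construction; ROC curves with tie-aware Mann-Whitney AUC;
  score-descriptor trends (equal-count bins + Spearman rank
  correlation); rank-sum class-selectivity comparisons with
  Benjamini-Hochberg adjustment.
* **Synthetic data with ground truth** — seeded generators for every
  input: correlated Cα trajectories with a known correlation matrix,
  staged helix-bundle-on-tube adsorption with brute-force contact
  counts, water boxes with programmed axial densities, fully
  parameterized toy complexes with brute-force reference energies, and
  132-odorant score tables with a known rise-then-fall volume response.

Everything runs on plain-text formats (multi-model PDB, XYZ, delimited
tables, YAML configs) with 1-based indices, Å, ps, and kcal/mol
throughout.

## Worked example

```r
library(cntmd)

# staged adsorption of a coarse helix bundle onto a nanotube
sched <- data.frame(from = c(1, 11, 21), to = c(10, 20, 30),
                    separation = c(12, 5, 1))
sim <- gen_adsorption_trajectory(sched, jitter = 0, seed = 42)
rec  <- select_atoms(sim$trajectory$system, "group:receptor and heavy")
tube <- select_atoms(sim$trajectory$system, "group:tube")
ads <- adsorption_series(sim$trajectory, rec, tube, cutoff = 6, stride = 10)
ads[, c("time", "adsorbed_atoms", "contact_area")]
#>   time adsorbed_atoms contact_area
#> 1    0              0      0.00000
#> 2   10              1     10.25226
#> 3   20             16    243.41256
```

As the programmed bundle-to-surface separation drops from 12 Å to 5 Å
to 1 Å, the number of receptor heavy atoms within the 6 Å criterion
steps 0 → 1 → 16 and the buried receptor-tube interface grows to
~243 Å² — the same staircase coupling of adsorbed atoms and contact
area seen in staged adsorption experiments.

```r
# screening statistics on a 132-odorant table with a volume turnover
odors <- gen_odor_table(n = 132, score_model = "turnover", seed = 42)
top44 <- top_fraction_subset(odors$records, "volume", fraction = 1/3)
roc <- roc_auc(odors$records, top44)
roc
#> roc_result: AUC = 0.5331 (44 positives, 88 negatives, more_negative_first)
trend <- descriptor_trend(odors$records, "volume", n_bins = 6)
trend$bins
#>   descriptor_mid mean_score  n
#> 1           65.1      -5.84 22
#> 2           90.6      -6.78 22
#> 3          129.5      -7.85 22
#> 4          166.1      -8.82 22
#> 5          208.1      -7.87 22
#> 6          242.8      -7.05 22
```

The binned mean docking score strengthens (grows more negative) with
molecular volume up to the programmed ~170 Å³ turnover, then weakens —
so ranking by score no longer enriches the 44 largest odorants, and the
AUC for the large-odorant subset falls to ~0.53, near chance. The
`top44` subset has exactly `floor(132/3) = 44` members.

A staged command-line front-end with YAML configs and run manifests is
installed at `inst/scripts/analyze.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "analyze.R", package = "cntmd"))')" \
    simulate --config run.yaml --seed 7 --out out/
```

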