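# cetpdyn

Structural-dynamics descriptors for conformational ensembles of two-domain
tunnel proteins, built around the analysis recipe used to characterise the
cholesteryl ester transfer protein (CETP) — a 476-residue plasma
glycoprotein whose banana-shaped fold shuttles cholesteryl esters and
triglycerides between lipoproteins through a putative hydrophobic tunnel.

## Who this is for

Computational structural biologists who have conformational ensembles
(multi-model PDB or XYZ trajectories, typically distilled from MD) and want
the standard descriptor battery for opening/closing and tunnel-formation
questions without gluing together five different tools:

- **Geometry** — Kabsch superposition; backbone RMSD, per-residue Cα RMSF,
  radius of gyration; *gate descriptors*: the maximum inter-residue
  atom-pair distances that quantify the N-opening (Trp106–Trp162), the
  C-opening (Phe301–Met412) and the tunnel neck (Phe265–Met433), with an
  open/closed flag at the 10 Å passage threshold; the Phe265 side-chain
  orientation angle (CZ–Cα(265)–Cα(260)); domain bend angles from
  principal axes.
- **Surface** — Shrake–Rupley SASA on a deterministic golden-spiral
  lattice, partitioned atom-wise into hydrophobic/hydrophilic classes and
  aggregated over the flexible-region registry (flaps Ω1–Ω6, Helix X,
  composite N-/C-terminal ends), plus alteration tables of signed
  fractional change against an initiating-conformation benchmark.
- **Cavity** — alpha-sphere pocket detection (circumspheres of an authored
  3-D Delaunay tetrahedralization, deflated by van der Waals radii),
  single-linkage pocket clustering, seeded Monte-Carlo union volumes,
  continuity classification (one continuous tunnel vs. fragmented
  cavities) and expansion rates over a trajectory.
- **Collective motions** — essential-dynamics PCA of Cα fluctuations
  (eigenvalues, variance fractions, porcupine vector fields) and dynamic
  cross-correlation matrices (DCCM), C_ij = ⟨Δr_i·Δr_j⟩ /
  √(⟨Δr_i²⟩⟨Δr_j²⟩) ∈ [−1, 1].
- **Energetics** — single-trajectory MM/GBSA rescoring:
  ΔG_bind = ΔE_ele + ΔE_vdw + ΔG_GB + ΔG_sur per snapshot
  (complex − receptor − ligand, entropy not computed), with Coulomb,
  Lennard-Jones (Lorentz–Berthelot), OBC-style generalized-Born polar
  solvation and γ·SASA + β nonpolar terms, averaged over snapshots drawn
  evenly from the trailing half of the trajectory; plus an auditor for
  published component tables (`check_gbsa_table`).
- **Synthetic ensembles** — deterministic generators with emitted ground
  truth: two-domain hinge ensembles with scripted bend/gate schedules and
  region-wise flexibility, cavity cages that fragment on schedule (void
  volumes certified by a rejection-sampling oracle), block-correlated
  anti-phase motions, and toy host–guest binding systems with parameter
  tables.
- **Pipeline** — `run_recipe()`/`compare_ensembles()` orchestrate
  everything into TSV report bundles with a parameter-echoing run log;
  reruns with the same config and seed are byte-identical.  A thin CLI
  (`inst/cli/cetpdyn`) exposes `analyze`, `compare`, `synthesize`, `gbsa`
  and `check-tables`.

## Worked example

```r
library(cetpdyn)

# a two-domain opening ensemble with a scripted gate (ground truth known)
fx <- make_hinge_ensemble(bend_schedule = seq(150, 130, length.out = 10),
                          gate_schedule = seq(8, 14, length.out = 10),
                          sigma = 0.1, seed = 1)

gate <- gate_distance_series(fx$ensemble, fx$truth$gate_resids[1],
                             fx$truth$gate_resids[2])
round(gate$values, 2)
#>  [1]  8.02  8.44  9.45  9.98 10.74 11.53 11.76 12.53 13.20 14.10
gate_open_flags(gate)     # >= 10 A lets a cholesteryl ester pass unrotated
#>  [1] FALSE FALSE FALSE FALSE  TRUE  TRUE  TRUE  TRUE  TRUE  TRUE

pca_modes(fx$ensemble)
#> collective_modes: 138 modes; PC1 98.9%, PC2 0.3%, PC3 0.2% of variance

g <- make_toy_binding_system(separations = c(4, 5, 6), seed = 1)
mmgbsa(g$ensemble, g$receptor, g$ligand, g$lj, snapshots = 1:3)
#> MM/GBSA over 3 snapshots (kcal/mol, entropy not computed):
#>   dE_ele   -68.26 +- 13.93
#>   dE_vdw    -0.11 +- 0.09
#>   dG_sur    -0.21 +- 0.18
#>   dG_GB     67.44 +- 13.43
#>   dG_bind   -1.14 +- 0.78
```

The gate series tracks the scripted 8 → 14 Å opening within the thermal
noise the generator injected, and flips "open" once the 10 Å passage
threshold is crossed.  PC1 carrying ~99% of the variance is the scripted
hinge motion.  In the toy complex the large Coulomb attraction is almost
cancelled by the generalized-Born desolvation penalty — the expected
physics for an ion pair entering low-dielectric contact.

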