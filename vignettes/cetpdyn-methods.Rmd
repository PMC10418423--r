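---
title: "Descriptor methods for two-domain tunnel-protein ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor methods for two-domain tunnel-protein ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cetpdyn)
```

cetpdyn implements the descriptor battery used to interrogate
conformational ensembles of CETP-like two-domain tunnel proteins: does a
lipid-passage opening form, does the interior cavity stay continuous, how
do the two β-barrel domains move collectively, and how strongly does a
ligand bind.  This vignette records the models behind each module, the
parameters that matter, the numerical choices made where the field's
conventions leave room, and what validation on synthetic ensembles does
and does not establish.

## Structures, typing and regions

Structures are held as flat atom tables (author residue numbering,
1-based, inclusive ranges; coordinates in Å, times in ns).  Multi-MODEL
PDB blocks become ensembles over a fixed topology; blocks that disagree in
atom count are rejected rather than reconciled.  Alternate locations keep
only blank/'A' conformers — a deliberate single-conformer policy.  HETATM
records are parsed and flagged but excluded by default, matching the usual
preparation of apo trajectories; `keep_hetero = TRUE` re-includes them for
ligand-bound work.

Atom typing assigns Bondi van der Waals radii and an *atomic*
hydrophobicity class: carbon, sulfur and halogens hydrophobic; N, O, P
hydrophilic.  Hydrogens inherit the class of their nearest heavy atom — a
distance proxy for the covalent partner, chosen because bond perception is
out of scope and the proxy is exact at bonded distances (~1 Å against van
der Waals contact at ≳2.4 Å).  Charges are never guessed: they enter only
through an explicit PQR-style table, because force-field parameter
assignment is a modelling decision the analyst must own.

The CETP region registry hard-codes the seven flexible regions (flaps
Ω1 290–318, Ω2 351–358, Ω3 392–404, Ω4 46–55, Ω5 100–111, Ω6 155–162, and
Helix X 465–476) with the composite N-terminal end = Ω4∪Ω5∪Ω6 and
C-terminal end = Ω1∪Ω2∪Ω3.  The N-domain/C-domain split used for bend
angles (1–240 / 241–464) is this package's own convention for the two
β-barrel halves either side of the central sheet; any other split can be
supplied as a custom region set.  One naming ambiguity is preserved
rather than resolved: crystal structures of the stabilised mutant lack
the first four residues and carry a C1A substitution, so position 1 of a
rebuilt wild-type model and of the crystal construct are different
chemical species; the registry works purely on residue numbers and takes
no side.

## Geometric descriptors

Superposition is the Kabsch algorithm (weighted SVD with a determinant
correction, so reflections are never returned).  Fewer than three points,
or a collinear reference, raises a degenerate-superposition error instead
of returning one of the infinitely many fits.

*Gate distances* are maxima over all inter-residue atom pairs.  The
default scope includes hydrogens when present, since the distances of
interest are computed on fully protonated MD models; `atom_scope =
"heavy"` serves raw crystal structures.  Whether a published "maximum
distance" included hydrogens is rarely stated — both scopes are exposed
and the choice is echoed in the run log.  Ties between equal-distance
pairs resolve to the first pair in file order, making reports
deterministic.  A frame is flagged "open" iff the gate distance is at
least the passage threshold, default 10 Å — the clearance a cholesteryl
ester's steroid ring needs to pass without reorientation.

*RMSF* is computed on Cα atoms about an iteratively refined mean
structure (two fitting passes); the iteration makes the reference
self-consistent without assuming any particular frame is representative.
*Bend angles* use the first principal axis of each domain's Cα cloud,
sign-fixed to point from the molecular centroid outward; `n_bend`/`c_bend`
measure each domain axis against the direction to the Helix X centroid and
`overall` the inter-domain angle.  Published "stretches/huddles by N°"
statements never define their construction; ours is declared as the
package's definition — deterministic, rotation-invariant, and validated
by recovering generator ground truth within 2° — not inferred as anyone
else's.  Exactly isotropic domains (no principal direction) error out.

## Surface accounting

SASA is Shrake–Rupley point counting with a probe of 1.4 Å (water) and
960 lattice points per atom, both field-standard defaults; the lattice is
a deterministic golden-spiral (Fibonacci) construction so areas carry no
sampling seed.  A point survives if it is not *strictly* inside any
neighbouring inflated sphere — boundary contact counts as exposed, a
deterministic tie-break.  Hydrophobic/hydrophilic partitioning happens at
the atom level (the partition is atomic, not per-residue), and per-region
class areas always satisfy hydrophobic + hydrophilic = total.

Alteration tables store *signed fractions* of an initiating-conformation
benchmark: a cell of −0.13 is prose "decreases by 13%".  Published tables
of this kind sometimes label fraction-valued cells as "(%)"; the package
stores fractions and renders either notation to avoid that ambiguity.
Whether a published alteration compares single frames or window means is
usually unstated; the operation takes explicit frames, and
`sasa_window_mean()` provides the window reducer.  Cells with a zero
benchmark area are an error, not an NA — regions lacking one atom class
should be filtered out deliberately (the pipeline does exactly that and
logs it).

## Cavity detection

Alpha-spheres are built on an authored incremental Bowyer–Watson Delaunay
tetrahedralization (no R package in scope provides one): each
tetrahedron's circumsphere, deflated by the mean van der Waals radius of
its four contact atoms, is a candidate; candidates survive with deflated
radius in [3, 6] Å by default, the usual window between packing
interstices and the unbounded hull spheres.  Two robustness choices
matter:

- A deterministic jitter of 10⁻⁵ × span breaks exactly cospherical or
  coplanar inputs (lattice-like shells make *every* interior tetrahedron
  cospherical, which no exact-arithmetic shortcut survives).
- Tetrahedra with a face on the convex hull are discarded by default
  (`discard_hull`): their circumspheres bulge outside the structure and
  otherwise register as spurious exterior pockets.

Pockets are single-linkage clusters of sphere centres at 4.5 Å; clusters
of fewer than 4 spheres are dropped as triangulation artefacts (the same
spirit as fpocket's minimum-sphere filter).  Pocket volume is a seeded
Monte-Carlo integral of the sphere union over the cluster bounding box
(10⁵ samples per pocket by default); identical inputs and seed give
identical volumes.  A cavity system is *continuous* iff exactly one
pocket exceeds the 100 Å³ minimum volume, else *fragmented* — continuity
is defined over consequential pockets only.  For expansion rates both
reducers are provided — endpoint (V_last − V_first)/V_first, the default,
and the mean over frames of (V_t − V_0)/V_0 — because published
"expansion rate" figures rarely say which they are.

## Collective motions

PCA diagonalises the 3N×3N covariance of Cα fluctuations; the trace
identity (Σλ = tr C) is enforced to 10⁻⁸ relative in tests.  DCCM uses
the isotropic scalar-product convention, C_ij = ⟨Δr_i·Δr_j⟩ /
√(⟨Δr_i²⟩⟨Δr_j²⟩), the cpptraj convention, noted in output headers.
Zero-variance atoms raise an error naming the residue rather than
silently contributing 0 — static fixtures should fail loudly.

Both operations superpose frames to the iteratively refined mean by
default (`fit = TRUE`).  The toggle exists because fitting *removes*
rigid-body components of motion: a synthetic ensemble whose blocks all
translate coherently has its entire signal absorbed by the fit, and the
apparent motion that survives fitting is redistributed about the
centroid, not about any physical hinge.  Lab-frame ensembles from the
generators are therefore analysed with `fit = FALSE` where the ground
truth is a lab-frame statement.  Eigenvector signs are fixed so each
mode's largest-magnitude component is positive; porcupine arrow
directions are convention-dependent in any tool, and this pins ours.

## MM/GBSA

Single-trajectory rescoring: receptor and ligand geometries are taken
from the complex frames, so internal-strain terms cancel exactly and
ΔG_bind = ΔE_ele + ΔE_vdw + ΔG_GB + ΔG_sur per snapshot by construction.
The entropy term −TΔS is deliberately not computed; reported totals are
the four-component sum, which is also what `check_gbsa_table()` audits in
published tables (the auditor's 0.05 kcal/mol default equals half a
printed decimal unit).

Defaults: ε_in = 1, ε_water = 78.5, k = 332.06 kcal·Å·mol⁻¹·e⁻²,
γ = 0.0072 kcal·mol⁻¹·Å⁻², β = 0.  Born radii come from the pairwise HCT
descreening integral with OBC-II tanh rescaling (α = 1, β = 0.8,
γ = 4.85) and a uniform descreening scale of 0.8.  The dielectric offset
is 0 Å — a deliberate departure from the common 0.09 Å — so that an
isolated ion's effective radius equals its intrinsic radius and the
module is exactly anchored to the Born closed form
ΔG = −(k/2)(1/ε_in − 1/ε_w) q²/R; with toy parameter sets (the only ones
the package ships) the offset carries no information anyway.  Snapshots
default to an even draw from the trailing half of the trajectory (up to
500), the usual production-window convention.  Coincident charged atoms
are a singularity error; the rescoring context needs no cutoffs.

## Synthetic ensembles: what they do and do not show

The generators are pure functions of their arguments and seed, and emit
the ground truth for every quantity the analysis later estimates
(schedule distances, bend angles, per-residue σ, oracle void volumes,
block signs).  Noise is isotropic per-atom Gaussian — a thermal-fluctuation
stand-in — with per-region amplitudes mapped from RMSF targets via
σ = RMSF/√3.  The cavity cage is a two-layer jittered Fibonacci shell; a
single exact shell is avoided because all its interior tetrahedra are
cospherical.  The delivered void volume is corrected analytically for
lattice discreteness and jitter so the rejection-sampling oracle lands on
the target (verified to 5%); fragmentation is scripted by regrouping the
shell atoms into two separated sub-cages (60 Å apart by default, far
enough that bridging tetrahedra fall outside the radius window).
Anti-correlated block motion runs along the axis joining block centroids,
which cancels both net translation and net torque, so the anti-phase
signal survives rigid-body fitting — it is a genuine internal mode.

Passing the recovery suite shows the estimators are *correct* on data
satisfying their assumptions: rigid domains, Gaussian noise, spherical
voids, pairwise-additive toy energetics.  It does not show robustness to
what real trajectories add — anharmonic and correlated noise, rugged
cavity topology, conformational substates, force-field limitations — and
no claim about real-protein accuracy is made from these fixtures.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run ensembles of 10–30 frames
over 40–170 atoms for geometry/PCA recovery, 800–5000 frames over 10–40
atoms for correlation statistics, and 480-atom cages for cavity work,
with 5×10⁴–10⁵ Monte-Carlo samples per pocket — sizes at which every
closed form and oracle in the suite is sharp.  All stochastic steps take
explicit seeds; `run_recipe()` echoes every effective parameter into its
run log, omits timestamps, and reruns with identical config and seed are
byte-identical.

## Known limitations

- PDB and plain XYZ only; no mmCIF or binary trajectory formats, no bond
  perception or protonation assignment.
- The Delaunay implementation is pure R and intended for desk-scale
  structures (≲10³ atoms per frame); whole-protein, all-atom cavity
  scans would want a compiled triangulation backend.
- Alpha-sphere tangency is exact only for equal contact radii; with mixed
  radii the deflation uses the mean radius, adequate inside the [3, 6] Å
  window where candidate spheres are much larger than the radius spread.
- MM/GBSA ships parameters only for its toy systems; real complexes
  require user-supplied PQR/LJ tables, and no entropy term is computed.
- The published component tables bundled under `inst/extdata/` are means
  ± sd rounded to one decimal; their row sums are audited, not recomputed
  from trajectories, since the underlying ensembles are not distributed.
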