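---
title: "Normal-mode-driven gating analysis of tetrameric channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal-mode-driven gating analysis of tetrameric channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdenm)
```

## The problem

Inward-rectifier potassium (Kir) channels are tetramers whose ion
conduction is controlled by a handful of constriction points near the
cytoplasmic end of the pore.  In KirBac3.1 these sit at Leu124, residue
129 (serine in the wild type, arginine in the activating S129R mutant)
and Tyr132.  Whether the channel conducts is, to a good approximation, a
question of geometry: a gate level is *open* when the shortest
diametrically opposed inter-chain atomic distance at that level exceeds
the diameter of an unhydrated K⁺ ion, 3.5275 Å.

`mdenm` implements a desk-scale version of the computational pipeline
used to study this gating equilibrium:

1. **Normal modes** of an elastic network, with a selection protocol
   that keeps the low-frequency modes that actually open or close the
   channel.
2. **MDeNM** (molecular dynamics with excited normal modes): replica
   Langevin simulations in which kinetic energy is periodically injected
   along fixed linear combinations of the selected modes.
3. **Clustering and relaxation**: the explored structures are clustered
   on the channel region (residues 121–133, 0.9 Å threshold),
   representatives are relaxed by free dynamics, and only the last three
   quarters of each relaxation trajectory are analysed.
4. **Gating analysis**: six shortest diametric distances per frame
   (124/129/132 × the (A,C) and (B,D) chain pairs), a five-state
   classification, population tables, TM1 kink angles, the
   cytoplasmic-domain rotation pseudo-dihedral, per-residue RMSF-like
   deviations and a simplified pore-radius profile.

A synthetic tetramer generator provides ground-truth-labelled ensembles
so that every stage of the pipeline can be validated quantitatively.

## The synthetic channel and what it does (not) emulate

`make_channel()` builds an idealized C4-symmetric tetramer with one CA
pseudo-atom per residue 35–295 per chain and an extra side-chain
pseudo-atom at each constriction residue, placed at a controlled radial
distance from the pore (z) axis: 4.0 Å for an open gate and 1.2 Å for a
closed one by default.  Because the two diametric side-chain atoms face
each other across the axis, a gate's shortest inter-chain distance is
twice its radius — 8.0 Å open, 2.4 Å closed — bracketing the 3.5275 Å
criterion with a margin the generator enforces to be at least three
noise standard deviations on each side.  The backbone trace is piecewise
simple: a slide helix (35–45), the TM1 outer helix (46–80) built from two
exactly straight sub-segments meeting at residue 56 with a configurable
kink (default 13°, in the range reported for the activated channel), a
turret/pore segment, the inner helix down to the bundle crossing
(121–133) and a cytoplasmic-domain spiral (134–295) that can be rotated
about the pore axis as a whole.

Two numerical choices deserve comment:

* **Corrugation.** All segments except TM1 are displaced by a
  deterministic 1 Å low-discrepancy offset per residue.  A literal
  stick-figure trace is locally collinear or coplanar, and an
  anisotropic elastic network built on such geometry has hundreds of
  spurious zero-frequency transverse modes; the corrugation restores a
  generic 3D neighbourhood so a connected network has exactly the six
  rigid-body zero modes.  TM1 is left exactly straight so that the kink
  angle of the generated structure is analytic.
* **CTD definition.** The rotation parameter is applied to residues
  134–295, i.e. strictly below the bundle crossing.  The rotation
  *measurement* (`ctd_rotation()`) is the pseudo-dihedral of the Leu108
  CA, its projection on the pore axis, the projection of the Ile266 CA,
  and that CA itself; keeping residue 108 outside the rotated block makes
  the generated rotation and the measured dihedral agree exactly, which
  is what the round-trip tests exploit.

`make_ensemble()` draws per-frame gating states i.i.d. from a
five-state probability vector (defaults: the wild-type reference mix;
`reference_populations("S129R")` gives the mutant-style two-state mix),
sets the gates accordingly and adds isotropic Gaussian coordinate noise
(default 0.15 Å).  What the generator deliberately does **not** emulate:
side-chain rotamers, sequence detail, membrane and solvent, and
inter-frame correlation — frames are exchangeable draws, because the
population table is a frame-wise fraction.  Passing tests on these
ensembles therefore validates the *operators* (distances, classifier,
angles, clustering), not the conformational kinetics of a real bilayer
simulation.

## Elastic network and mode selection

`build_hessian()` constructs the standard anisotropic network model:
every atom pair within 12 Å interacts through a Hookean spring (uniform
force constant, default 1 kcal mol⁻¹ Å⁻²), giving 3×3 blocks
\(-k\,\hat r_{ij}\hat r_{ij}^{\mathsf T}\) and a diagonal that satisfies
the translational sum rule exactly.  Masses are optional; with them the
Hessian is mass-weighted and eigenvalues are squared angular
frequencies (the two-body system then oscillates at \(2k/m\), one of
the closed-form checks in the tests).  `compute_modes()` is a dense
symmetric eigendecomposition; modes come out in ascending order and
rigid-body modes are flagged by an eigenvalue below \(10^{-8}\) of the
spectral maximum.

`select_gating_modes()` follows the selection protocol: displace the
structure ±2 Å RMSD along each non-rigid mode, score the mode by the
largest change of the diametric residue-125 pair distances, keep the
ten highest-scoring modes, classify the opening shape, drop redundant
modes, and keep the four lowest-frequency survivors.  Two parts of that
protocol are qualitative in the original description, so this package
defines them explicitly (both configurable and recorded in the
selection table):

* **Shape**: let \(\delta_1, \delta_2\) be the signed changes of the two
  diametric pair distances at +2 Å.  Same sign with
  \(\min|\delta|/\max|\delta| \ge 0.5\) is *spherical*; same sign with a
  smaller ratio, or opposite signs with both above a 0.1 Å noise floor,
  is *elliptical*; anything else is *other* and is excluded.
* **Redundancy**: two modes whose channel-region sub-vectors have
  absolute cosine similarity above 0.9 are redundant; the
  higher-frequency one is dropped.

Scores use absolute distance changes, so selection is invariant to the
arbitrary sign of eigenvectors.

## Excited dynamics

`combine_modes()` samples coefficient vectors uniformly on the unit
hypersphere of the selected-mode subspace.  Because the mode vectors are
orthonormal, the RMSD between two structures displaced 1 Å along two
directions equals the chord distance between their coefficient vectors,
so "uniformly spread directions" becomes a minimum-spacing rule on the
sphere: a candidate is rejected if it comes closer than 0.8 times the
covering-heuristic spacing \(2(1/n)^{1/(m-1)}\) to an accepted one.
With one selected mode the only two directions are ±v.

`excite()` adds a velocity increment along the (mass-unweighted)
direction scaled so the increment's kinetic energy alone equals
\(\tfrac32 n_\text{atoms} k_B\,\Delta T\) with \(\Delta T = 4\) K by
default — the defining equation is solved in closed form, so the
bookkeeping is exact to rounding.  `run_replica()` applies one
excitation at \(t=0\) and one after each 1 ps relaxation interval, ten
in total, within Langevin dynamics at 300 K (BAOAB splitting, 2 fs
step, friction 1 ps⁻¹, 3·n degrees of freedom for the temperature since
the toy systems have no constraints).  The integrator's inner loop is
compiled (Rcpp); the elastic network is stored as a spring pair list,
which keeps a 5000-step replica of the 1056-atom default channel under
a few seconds.  All randomness derives from the configured seed, so
replicas are bit-reproducible.

The recording stride (default: every 50 steps) and whether excitation
directions are mass-weighted before normalization are not fixed by the
protocol's published description; both are explicit configuration here
(directions are normalized in plain Cartesian coordinates, which for
the generator's uniform 110 amu pseudo-atoms coincides with the
mass-weighted choice).

### The double-well exploration fixture

To test that excitation explores what plain thermal dynamics cannot,
`double_well_potential()` decouples the four side-chain pseudo-atoms of
one constriction residue (129 by default) from the network and gives
each a quartic double well along its chain's radial direction with
minima at the closed (1.2 Å) and open (4.0 Å) gate radii, a 7 kcal/mol
barrier (≈ 11.7 \(k_BT\) at 300 K; the height was set empirically, since
the quartic well's soft shoulder gives thermal excursions much fatter
tails than a harmonic estimate suggests), and 10 kcal mol⁻¹ Å⁻²
harmonic restraints on the tangential and axial directions.  Ten 4 K
excitations of the 1056-atom system inject ≈ 12.6 kcal/mol each; aimed
along the four-atom radial breathing direction this is ≈ 3.1 kcal/mol
per gate atom per kick, which reliably drives the gates over the
barrier, while equal-length unexcited runs stay in the closed basin.

## Clustering, relaxation, analysis

`cluster_frames()` is the greedy leader algorithm on channel-region
RMSD: the first frame seeds cluster 1, each subsequent frame joins the
nearest leader within 0.9 Å or seeds a new cluster, so unique
structures survive as singletons.  Whether frames should be superposed
before the region RMSD is not fixed by the protocol; by default each
frame is first fitted on all CA atoms (so the metric reflects internal
channel geometry, not rigid drift), and `superpose = FALSE` gives the
pore-axis-frame alternative.  Representatives are re-chosen as the
member closest to the cluster's average structure; with well-separated
basins this preserves the pairwise spacing guarantee of the leaders,
which the tests check explicitly.

`relax()` runs unexcited Langevin dynamics from each representative and
keeps exactly the last three quarters of each trajectory (drop the first
⌈0.25 n⌉ recorded frames; ties resolved by dropping the earlier frame).
Kept frames carry provenance (representative, frame, step) and their
instantaneous kinetic temperatures, which equilibrate to the bath value
within 5% on the harmonic network.

`classify_state()` applies the ionic-diameter criterion with a strict
inequality (a distance exactly equal to 3.5275 Å is closed) and, by
default, the *min* rule: a gate is open only if **both** diametric pairs
clear the diameter, since an ion cannot pass a gate closed on either
diagonal.  The `either` rule is available for sensitivity analysis.
The decision order puts the two principal gates first: both open →
fully open unless the 129 level is closed (the "gating 129 closed"
state); one open → the corresponding partially open state; both closed →
fully closed.  The 129-closed label is only assigned when 124 and 132
are both open, matching a taxonomy in which the wild type never occupies
it and the activated mutant's only closed category is at 129; the
classifier additionally reports the raw open/closed status of every
level in the `gate_open` attribute.  Percentages in
`population_table()` always sum to 100 within rounding.

`kink_angle()` measures the angle between the principal axes of the CA
sub-segments 46–56 and 56–80, oriented N→C; a principal-axis fit is
robust to helical winding, and an endpoint-vector mode is available for
comparison.  `ctd_rotation()` is the four-point pseudo-dihedral
described above, reported in (−180°, 180°].  `per_residue_rmsd()`
implements \(\mathrm{RMSD}_i = \sqrt{\frac1N \sum_n |r_i(n) -
r_i^\mathrm{ref}|^2}\) per atom, averaged over each residue's atoms,
with no superposition unless requested (the choice is recorded in the
result); the reference — a supplied structure or the ensemble mean — is
an explicit argument because either convention is defensible.
`pore_radius_profile()` reports, per z-slab, the minimum over in-slab
atoms of (axis distance − atom radius), floored at zero; it is a fast
constriction profile, not a sphere-maximization pore tracer.

Hydrogens are retained whenever input files contain them and every
analysis object records whether they were present, because shortest
atomic distances shift systematically between heavy-atom and all-atom
structures; the synthetic generator is heavy-pseudo-atom only and its
reports say so.

## Problem sizes and determinism

The validation suite and the acceptance script run entirely on
synthetic structures: the default 1056-atom tetramer for mode analysis
(dense 3168×3168 eigendecomposition, a few seconds), ensembles of
1000–10000 frames for classifier and population checks, twenty paired
10 ps replicas for the exploration contrast, and a 20 ps relaxation for
the temperature check.  These sizes were chosen so each property is
measured with comfortable statistical margin while the whole suite runs
in minutes on one core.  Every stochastic step — ensemble generation,
direction sampling, thermal noise — is driven by explicit seeds, and
reruns are bit-identical, which the tests assert.

## Known limitations

* The elastic network is harmonic; anharmonic gating thermodynamics
  enters only through the explicitly constructed double-well fixture.
* Populations estimated from synthetic ensembles validate the
  classifier, not the physics that produced a given experimental
  population split.
* The pore profile assumes the pore axis is z; for tilted inputs,
  estimate the axis from the four-fold symmetry with
  `estimate_pore_axis()` and rotate the structure onto z with
  `transform_structure()` (or pass the axis to `ctd_rotation()`
  directly).
* Crystal-symmetry assembly is idealized C4; true crystallographic
  asymmetry between chains is representable only through per-chain
  parameters (e.g. per-chain kink angles).
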