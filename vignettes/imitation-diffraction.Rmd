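---
title: "Simulating rotation-series diffraction photographs from atomic ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rotation-series diffraction photographs from atomic ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xrdsim)
```

## The physical model

The simulator treats every atom of a crystal supercell as a source of a
secondary wavelet. With the incident beam along lab +z and wavevectors in
the cycles-per-angstrom convention (|k| = 1/λ), the pixel collecting
scattered direction k′ receives, from one snapshot,

    A_total(p) = Σ_j o_j f_j(s(p); B_j) exp[i 2π r_j · (k − k′(p))]

and the recorded frame intensity is Σ |A_total|² accumulated over every
angular sub-step of the oscillation frame and every ensemble snapshot.
The two accumulation rules are deliberate and asymmetric to phase:
within one snapshot, atoms interfere coherently (complex sum); across
snapshots and sub-steps, only intensities add, the way exposure
accumulates on a real detector. A duplicated snapshot therefore exactly
doubles every pixel — the suite asserts this to machine precision.

Assumptions baked into the model:

* **Far field.** Wavelets are plane waves; no 1/R² decay, no
  solid-angle, Lorentz, polarization or air-absorption corrections are
  applied to the raster. (A Lorentz correction *is* applied at the
  data-reduction stage, where it belongs; see below.)
* **Real scattering factors.** No anomalous dispersion, which makes
  Friedel symmetry I(q) = I(−q) an exact invariant — tested at 1e−10
  relative on random ensembles.
* **B = 0 by default.** When the input is an ensemble of snapshots, the
  small-amplitude motion lives in the coordinates; folding it into a
  Debye–Waller factor as well would double-count it. Per-atom B factors
  from a static PDB can be honored with `use_b = TRUE`.
* **Occupancy multiplies amplitude**, so partial-occupancy sites in real
  structures behave conventionally, and a Gaussian occupancy envelope
  can stand in for a soft-edged crystal (see the merging experiment).

The wavevector convention is chosen so that the phase 2π r·(k−k′) is in
radians with no hidden 2π, and s = |k−k′|/2 is directly the
sinθ/λ argument of the form-factor tables.

## Scattering factors

Form factors use the International Tables 4-Gaussian-plus-constant
parameterization, shipped as a CSV asset for H, C, N, O, Na, Mg, P, S,
Cl (plus the chloride ion), K, Ca, Fe and Zn; `load_scattering_table()`
accepts a replacement table in the same layout. The shipped coefficients
satisfy f(0) ≈ Z to within 0.1 e (asserted per element), and hydrogens
are included in all sums — their contribution is small but not zero.

## Geometry and the rotation protocol

The detector is flat, perpendicular to the beam, with 0-based pixel
indices, the fast axis horizontal, and amplitudes evaluated at pixel
centers; the crystal rotates about lab x. A `rotation_series` fixes
(start, frame width, sub-step ΔΩ, total range); the reference protocol is
180 frames of 1° built from ten 0.1° sub-steps. Sub-step angles sit at
sub-step midpoints: the midpoint rule gives unbiased angular coverage
and, for the smooth rocking curves encountered here, converges faster
than edge placement.

Defaults that are genuinely free parameters: pixel pitch and beam center
are never implied by the model and must come from configuration (the
reference raster is 487 × 407 pixels at 45 mm). The crystal orientation
is always a user-supplied proper rotation — the package deliberately
does not guess orientations from data.

## The FFT cross-engine

`fft_photograph` grids each snapshot's electron density with Gaussians
matching the form-factor terms, Fourier-transforms once per snapshot,
and interpolates the transform onto the Ewald sphere for every sub-step.
Numerical choices that matter:

* **Band-limiting blur.** Every Gaussian term (and the constant term) is
  broadened by an extra B of 8π²(0.9h)² Ų for grid spacing h, then the
  blur is divided out at lookup. This keeps the narrowest density
  features ≳ 0.9 grid cells wide, so aliasing from sampling the Gaussian
  tails stays below ~0.3% per term at the resolutions probed.
* **Center-referenced transform.** Phases are referenced to the box
  center (checkerboard factor on the FFT output), so the stored
  transform varies on the scale of the inverse crystal extent rather
  than the inverse box size; without this the interpolation error is
  catastrophic.
* **Cubic interpolation, 4× padding.** Catmull–Rom interpolation of the
  complex transform over a box padded to 4× the crystal extent holds the
  cross-engine deviation on a 125-atom toy crystal to ~0.1% relative
  RMS (the suite requires < 2%, and separately that halving the grid
  spacing reduces the deviation). A grid too coarse for the requested
  resolution (h > d_min/3) is rejected with the implied d_min.
* **Accumulation mode.** By default the FFT path mirrors the direct
  engine (per-snapshot |F|², then sum). The amplitude-averaged-density
  variant is exposed as `average_amplitude = TRUE` and documented as
  different for dynamic ensembles: averaging F before squaring keeps
  only the Bragg component and suppresses diffuse scattering, which the
  suite demonstrates as a strict intensity deficit off-peak.

Performance: the per-pixel sum is evaluated as a (pixels × atoms) phase
product in blocks bounded by `options(xrdsim.block_elements)` (default
4e6 matrix elements), and `simulate_series` logs one line per frame.

## Data reduction: prediction, integration, merging

`predict_reflections` solves the Ewald condition in closed form for each
index triple (rotation about x gives a cos/sin equation per reflection)
and records, besides the pixel and frame of each crossing, the crossing
speed |dq_z/dω| — the reciprocal of the rotation-method Lorentz factor.
Integration is deliberately simple summation with a median-background
annulus: deterministic, testable, and sufficient for relative
comparisons; there is no profile fitting, no partial-reflection
splitting across frames (boundary-adjacent crossings are flagged
partial instead), and negative integrated intensities are kept so the
merging statistic reflects integration noise honestly. R_merge groups
observations by the canonical symmetry equivalent (lexicographic maximum
of the point-group orbit, Friedel mates included by default), uses only
multiplicity ≥ 2 groups, and drops groups with non-positive sums (count
reported). It is scale-invariant and matches an independent two-pass
oracle to 1e−12 in the suite.

## The oscillation-sampling experiment

`delta_omega_experiment` probes, at desk scale, how R_merge degrades
when the sub-step used to build each oscillation frame is coarsened.
At full experimental scale this effect is measured on a solvated
125-unit supercell processed by an external integration program; a
desk-scale crystal and the in-house summation integrator cannot
reproduce those magnitudes, so the experiment asserts the monotone
trend across sub-steps, never particular values. Design choices, all
visible as function defaults:

* The crystal is a 12³ point lattice (10 Å spacing) under a Gaussian
  occupancy envelope of σ = 30 Å. The envelope gives Gaussian rocking
  curves ~1° wide — narrow enough that a frame-width sub-step samples
  each curve at essentially one arbitrary offset (equivalents disagree
  wildly), a tenth-width sub-step undersamples it measurably, and a
  hundredth-width sub-step integrates it accurately.
* Frames are wide (30° over a 90° range) so that whole rocking curves
  fit inside one frame; crossings within 3° of a frame boundary are
  excluded rather than split.
* Integrated intensities are multiplied by the crossing speed (Lorentz
  correction). Without it the fine-sub-step limit has an irreducible
  scatter floor: symmetry equivalents cross the Ewald sphere at
  different speeds and their rocking integrals differ systematically
  even for identical structure factors.
* Standard rejection filters precede merging: grazing passages
  (dimensionless obliquity < 0.2), spot collisions (centers closer than
  18 px in the same frame, checked against *all* predicted spots on the
  image, not just the analysis shell), and raster-edge windows.

With these conditions the three sub-steps (frame width, /10, /100) give
strictly decreasing R_merge with large margins; the suite asserts the
strict ordering only, never the values.

## Ensemble metrics

Best-fit superposition is a native Kabsch/SVD solve (row-vector
convention, proper rotation enforced); the suite cross-checks it against
an independent quaternion (Horn) oracle and against bio3d's least-squares
fit. Lattice alignment translates centers of mass only, so molecular
displacement and reorientation within the lattice remain in the metric —
lattice r.m.s.d. ≥ best-fit r.m.s.d. frame by frame is asserted as an
invariant. For r.m.s.f., fluctuations are taken about each molecule
copy's own mean position and pooled over copies and frames; the per-copy
mean is the only choice that makes sense for lattice mode (copies occupy
different lattice sites) and is used for both modes for consistency.
Periodic-jump correction precedes lattice-mode analysis: a molecule
whose center moves by more than half a box vector between consecutive
frames is shifted by the minimizing integer box translation from that
frame onward.

B factors convert by B = (8π²/3)·r.m.s.f.², valid for isotropic Gaussian
fluctuations. The same constant is probed through the diffraction
engine: a Gaussian-displacement ensemble (σ = 0.3 Å, 256 frames) of a
point lattice must yield a log-intensity-ratio regression slope
recovering B = 8π²σ² within 10% — tying the real-space and
reciprocal-space faces of the same assumption together.

Ordered-water matching follows the hydrogen-bond rule: two structures
share a water when each has a water hydrogen-bonded to the same protein
atom in the same capacity (donor or acceptor); any one shared
(partner, capacity) pair suffices. Assignment is greedy 1:1 by partner
overlap with ties broken by O–O distance. When waters or protein donors
carry no hydrogens, an H is placed along the donor→acceptor direction at
1.0 Å — a geometric stand-in that reduces the donor test to the distance
criterion; results carry a `hydrogens_placed` flag so downstream users
know which regime produced them.

## Crystal construction

Symmetry operators ship as data (triplet strings) for P1 and P43212;
any group can be supplied as explicit triplets, and the parser handles
the usual ±x/±y/±z and rational-translation grammar. Expansion
fractionalizes, applies the operator, and orthogonalizes (a along x, b
in the x–y plane) with no wrapping into the cell, so each copy is an
exact rigid motion of the asymmetric unit — intra-molecule distances are
preserved to 1e−9 Å by construction and by test. Group closure of the
shipped P43212 operators is asserted directly.

Solvation places rigid 3-site waters (O–H 1.0 Å, H–O–H 109.47°) with
uniform random position and orientation, rejection-sampled against a
minimum oxygen–heavy-atom distance (default 2.4 Å); the geometry is a
fixture convention, not a force-field claim. Neutralization derives the
net formal charge from an explicit per-residue table (defaults: Arg/Lys
+1, Asp/Glu −1, neutral His; protonation variants are just table
entries) because predicting protonation is out of scope; chain termini
are not treated separately, which is net-neutral for zwitterionic
chains. The per-protein formal charge that a real system carries is
deliberately configuration, not a constant.

## What the synthetic generators do and do not emulate

The fixture generators supply deterministic, seed-reproducible inputs:
point lattices (closed-form interference tests), toy asymmetric-unit
crystals (symmetry and merging tests), Gaussian-displacement ensembles
(the statistical structure the B-factor relation assumes), and synthetic
binary templates (grafting tests). A Gaussian-displacement ensemble has
no correlated motion, no rotameric jumps, no lattice drift and no
solvent dynamics; passing the Debye–Waller and r.m.s.f. checks on it
shows the estimators are correct under the model's own assumptions, not
that real trajectories satisfy those assumptions. Likewise the
soft-edged point-lattice crystal isolates sampling effects in the
merging experiment; it says nothing about mosaicity, absorption or
detector noise, all of which are out of scope here.

## Problem sizes

The suite and the acceptance script run at sizes chosen for a single
CPU: oracle equivalence at 50 atoms × 100 pixels; cross-engine
validation on a 125-atom crystal over a 49² raster; the Debye–Waller
regression at 216 atoms × 256 frames × 12 Bragg peaks; the merging
ladder at 1728 atoms, three 30° frames and ~19 analysed reflections.
The full suite completes in a few minutes; the acceptance script in
about two.

## Known limitations

* No instrumental noise, background, point-spread or mosaicity models;
  no polarization or absorption corrections.
* The FFT engine holds the whole padded grid in memory; very large
  supercells belong to the direct engine's blocked evaluation.
* The merging experiment's magnitudes depend on its filtering choices;
  only the ordering across sub-steps is a stable claim.
* Water matching with placed hydrogens cannot distinguish donor from
  acceptor geometry beyond the distance criterion.
* Space groups beyond P1/P43212 rely on user-supplied operator strings;
  there is no general space-group engine.
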