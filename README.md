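# xrdsim

Simulation of rotation-series X-ray diffraction photographs from atomic
coordinate ensembles of a protein crystal supercell, pixel by pixel, by
direct summation of atomic wavelets (Huygens–Fresnel principle).

## Who this is for

Structural biologists and methods developers who want to generate
realistic oscillation photographs from explicit atomic models — a static
crystal structure or an ensemble of supercell snapshots standing in for
molecular-dynamics frames — and push them through the standard
crystallographic bookkeeping: detector geometry, oscillation frames,
image export, Bragg-spot prediction and integration, symmetry merging,
and ensemble-dynamics metrics (B factors, r.m.s.d./r.m.s.f., ordered
waters).

## The model

Each atom *j* at position **r**_j scatters the incident plane wave
(wavevector **k**, |**k**| = 1/λ) as a secondary wavelet. At the detector
pixel that collects direction **k**′, the atom contributes with phase
δ_j = 2π · **r**_j · (**k** − **k**′), so the resultant amplitude is

    A_total(p) = Σ_j  o_j · f_j(s; B_j) · exp(i δ_j)

where o_j is the occupancy and f_j the atomic form factor at
s = |**k** − **k**′|/2 = sinθ/λ, parameterized as the International
Tables 4-Gaussian sum plus constant, damped by exp(−B_j s²). The
photograph intensity accumulates |A_total|² over every rotation sub-step
of the oscillation frame and over every ensemble snapshot — intensities
add, never complex amplitudes across snapshots, exactly as exposure
accumulates in a real experiment. Scattered wavelets are treated as
plane waves (far field); instrumental noise and background are out of
scope. An FFT engine (density gridding → Fourier transform → Ewald-sphere
interpolation) provides an independent cross-validation path.

Supporting modules: space-group expansion of an asymmetric unit
(P1 and P43212 shipped; arbitrary operator triplets accepted), supercell
replication, random solvation and neutralization; SMV image export and
grafting of simulated arrays into existing detector-file templates;
Ewald-sphere reflection prediction, summation integration with median
background, and the merging statistic
R_merge = Σ|I_i − ⟨I⟩| / ΣI_i over symmetry equivalents; periodic-jump
correction, best-fit (Kabsch) and lattice r.m.s.d./r.m.s.f.,
B = (8π²/3)·r.m.s.f.², and ordered-water matching by hydrogen-bond
criteria (D–A < 3.5 Å, D—H⋯A > 150°).

## Worked example

```r
library(xrdsim)

## a tetragonal lysozyme-like crystal: asymmetric unit -> unit cell ->
## 5 x 5 x 5 supercell
cell <- unit_cell(78.67, 78.67, 36.93)
sg   <- space_group("P43212")
asu  <- make_toy_asu_crystal(space_group("P1"), cell, c(1, 1, 1),
                             n_atoms = 12, seed = 7)
cellset <- expand_asymmetric_unit(asu, sg, cell)
cellset
#> <atom_set> 96 atoms, 8 molecule(s), elements: C O S
supercell <- build_supercell(cellset, supercell_spec(5, 5, 5, cell, sg))
length(unique(supercell$mol))
#> [1] 1000

## the standard rotation protocol: 180 one-degree frames, each built
## from ten 0.1-degree sub-steps
series <- rotation_series(0, 1, 0.1, 180)
series
#> <rotation_series> 180 frames x 1 deg (substep 0.1 deg), start 0 deg

## simulate one frame of a small test lattice on a coarse detector
lat   <- make_point_lattice(5, 5, 5, 6)
small <- detector_geometry(1.54, 45, 1.0, c(49, 49), c(24, 24))
ph <- simulate_frame(lat, small, rotation_series(0, 1, 0.5, 1),
                     frame_index = 0)
ph
#> <photograph> frame 0 [0, 1) deg, 49x49 px, 1 snapshot(s), engine=direct
c(max(ph$intensity), median(ph$intensity))
#> [1] 1.1247e+06 2.5927e+01      # sharp Bragg peaks over weak background

## the B-factor / fluctuation relation
b_from_rmsf(1)
#> [1] 26.31895                   # 8 pi^2 / 3, for rmsf = 1 A
```

The 96 atoms of the expanded cell are the 8 symmetry copies of the
12-atom asymmetric unit; 8 copies × 125 cells give the 1000 molecules of
the supercell. The frame intensity spans ~5 orders of magnitude between
Bragg peaks and the inter-peak background, which is what makes the
scaling scan (`scan_scaling`) necessary before 16-bit export.

A thin command-line front end is installed at `inst/cli/xrdsim`
(subcommands `build`, `simulate`, `export`, `integrate`, `merge`,
`fixtures`); run configurations are YAML files read by
`read_run_config()`.

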