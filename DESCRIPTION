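Package: xrdsim
Title: Simulation of Rotation-Series X-Ray Diffraction Photographs from
    Atomic Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates rotation-series X-ray diffraction photographs
    pixel-by-pixel from atomic-coordinate ensembles of a protein crystal
    supercell by direct Huygens-Fresnel summation of atomic wavelets, with
    an FFT-based density-gridding engine for cross-validation. Includes
    supercell construction from space-group symmetry, International Tables
    atomic form factors with Debye-Waller damping, detector geometry and
    oscillation-frame bookkeeping, SMV detector-image export and
    template-array grafting, Ewald-sphere reflection prediction with spot
    integration and symmetry merging (R_merge), and ensemble-dynamics
    metrics (best-fit and lattice r.m.s.d./r.m.s.f., B factors, and ordered
    water matching by hydrogen-bond criteria).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
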