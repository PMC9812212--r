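# Deterministic generators for test inputs: toy crystals, Gaussian
# displacement ensembles, solvated ideal supercells and template image
# files.  Every fixture regenerates byte-identically from (kind,
# parameters, seed); no binary blobs ship with the package.

#' Regular lattice of point scatterers
#'
#' Atoms of one element at integer grid points with the given spacing,
#' B = 0 — the carrier for closed-form interference tests (the finite
#' lattice sum along one axis is sin^2(N pi u)/sin^2(pi u)).
#'
#' @param n_a,n_b,n_c grid counts (>= 1).
#' @param spacing lattice spacing, angstrom.
#' @param element element symbol (default `"C"`).
#' @param envelope_sigma optional Gaussian crystal-envelope width,
#'   angstrom: occupancies fall off as `exp(-r^2 / (2 sigma^2))` from the
#'   lattice center, giving a soft-edged crystal with Gaussian-shaped
#'   Bragg spots (no sharp-boundary shape-transform tails).
#' @return an `atom_set`; all atoms share molecule index 1.
#' @export
make_point_lattice <- function(n_a, n_b, n_c, spacing, element = "C",
                               envelope_sigma = NULL) {
  stopifnot(n_a >= 1, n_b >= 1, n_c >= 1, spacing > 0)
  g <- expand.grid(x = seq_len(n_a) - 1L, y = seq_len(n_b) - 1L,
                   z = seq_len(n_c) - 1L)
  out <- atom_set(data.frame(
    element = element, name = element, resname = "LAT",
    resno = 1L, chain = "A", mol = 1L,
    x = g$x * spacing, y = g$y * spacing, z = g$z * spacing,
    occ = 1, b = 0, stringsAsFactors = FALSE))
  if (!is.null(envelope_sigma)) {
    stopifnot(envelope_sigma > 0)
    ctr <- colMeans(coords(out))
    r2 <- rowSums(sweep(coords(out), 2, ctr)^2)
    out$occ <- exp(-r2 / (2 * envelope_sigma^2))
  }
  out
}

#' Random compact pseudo-peptide asymmetric unit, expanded and replicated
#'
#' Builds a seeded random asymmetric unit (~`n_atoms` heavy atoms within
#' a compact ball, elements drawn from C/N/O/S), expands it by the space
#' group and replicates it into the requested supercell — the desk-scale
#' analogue of an ideal crystal supercell fully obeying its symmetry;
#' optional random waters via [solvate_random()].
#'
#' @param sg a [space_group()].
#' @param cell a [unit_cell()].
#' @param n_rep length-3 replication counts.
#' @param n_atoms atoms in the asymmetric unit.
#' @param seed integer seed.
#' @param n_waters random waters added to the final supercell (0 = none).
#' @return an `atom_set`.
#' @export
make_toy_asu_crystal <- function(sg, cell, n_rep = c(1, 1, 1), n_atoms = 20,
                                 seed = 1, n_waters = 0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  radius <- min(cell$a, cell$b, cell$c) / 6
  center <- as.vector(orthogonalization_matrix(cell) %*% c(0.15, 0.15, 0.15))
  pts <- matrix(0, n_atoms, 3)
  for (i in seq_len(n_atoms)) {
    repeat {
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) <= radius^2) break
    }
    pts[i, ] <- center + p
  }
  el <- sample(c("C", "C", "C", "N", "O", "S"), n_atoms, replace = TRUE)
  asu <- atom_set(data.frame(element = el, name = el, resname = "TOY",
                             resno = 1L, chain = "A", mol = 1L,
                             x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             occ = 1, b = 0, stringsAsFactors = FALSE))
  cellset <- expand_asymmetric_unit(asu, sg, cell)
  out <- build_supercell(cellset, supercell_spec(n_rep[1], n_rep[2], n_rep[3],
                                                 cell, sg))
  if (n_waters > 0) {
    box <- c(n_rep[1] * cell$a, n_rep[2] * cell$b, n_rep[3] * cell$c)
    out <- solvate_random(out, box, n_waters, seed = seed + 1L)
  }
  out
}

#' Gaussian-displacement ensemble
#'
#' Each frame displaces every atom of the base structure independently by
#' an isotropic 3-D Gaussian with per-axis standard deviation `sigma` —
#' the statistical structure assumed by the B = (8 pi^2 / 3) rmsf^2
#' relation (isotropic harmonic motion). Deterministic per seed.
#'
#' @param base an `atom_set`.
#' @param sigma 1-D standard deviation, angstrom (>= 0).
#' @param n_frames_out number of frames (>= 1).
#' @param seed integer seed.
#' @return an `ensemble`.
#' @export
make_gaussian_ensemble <- function(base, sigma, n_frames_out, seed = 1) {
  stopifnot(sigma >= 0, n_frames_out >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  xyz <- coords(base)
  arr <- array(0, dim = c(nrow(xyz), 3, n_frames_out))
  for (f in seq_len(n_frames_out))
    arr[, , f] <- xyz + stats::rnorm(length(xyz), sd = sigma)
  ensemble(base, arr)
}

#' Synthetic detector-file template for grafting tests
#'
#' A self-consistent binary file (raw vector): a dummy ASCII header
#' padded to 512 bytes, followed by seeded random 16-bit little-endian
#' data, plus the data-array descriptor locating the array and an
#' optional preserve mask marking "beamstop"-like regions.
#'
#' @param raster length-2: (n_fast, n_slow).
#' @param mask_frac fraction of pixels marked as preserved regions.
#' @param seed integer seed.
#' @return list with `bytes` (raw), `descriptor`, `preserve_mask`
#'   (logical matrix).
#' @export
make_template_image <- function(raster, mask_frac = 0.02, seed = 1) {
  stopifnot(length(raster) == 2, all(raster >= 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  npx <- prod(raster)
  head_txt <- sprintf("{\nTEMPLATE=synthetic;\nSIZE1=%d;\nSIZE2=%d;\n}\n",
                      raster[1], raster[2])
  hb <- charToRaw(head_txt)
  hb <- c(hb, rep(charToRaw(" "), 512 - length(hb)))
  data <- sample.int(65536L, npx, replace = TRUE) - 1L
  mask <- matrix(FALSE, raster[1], raster[2])
  mask[sample.int(npx, max(0L, round(mask_frac * npx)))] <- TRUE
  list(bytes = c(hb, .uint16_le_encode(data)),
       descriptor = list(offset = 512L, length = 2L * npx, type = "uint16_le"),
       preserve_mask = mask)
}
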