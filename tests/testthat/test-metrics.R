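# independent quaternion (Horn) superposition oracle: optimal RMSD via the
# largest eigenvalue of the 4x4 key matrix -- no SVD, no shared code
oracle_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  m <- crossprod(ac, bc)
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  key <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(key, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(ac^2) + sum(bc^2) - 2 * lam) / nrow(a)
  sqrt(max(0, msd))
}

test_that("periodic-jump correction restores continuous trajectories", {
  base <- random_atom_set(6, span = 3, seed = 28)
  box <- c(30, 30, 30)
  # identity on a jump-free ensemble
  ens <- make_gaussian_ensemble(base, 0.1, 4, seed = 29)
  expect_equal(unwrap_periodic(ens, box)$coords, ens$coords)
  # a molecule displaced by exactly +box_x in frame 2 is pulled back
  arr <- array(rep(coords(base), 3), dim = c(6, 3, 3))
  arr[, 1, 2] <- arr[, 1, 2] + 30
  wrapped <- ensemble(base, arr)
  fixed <- unwrap_periodic(wrapped, box)
  expect_equal(fixed$coords[, , 2], fixed$coords[, , 1], tolerance = 1e-12)
  expect_equal(fixed$coords[, , 3], fixed$coords[, , 1], tolerance = 1e-12)
})

test_that("unwrapping matches a cumulative-shift-tracking oracle", {
  set.seed(30)
  n_at <- 4; nf <- 30; box <- c(20, 25, 15)
  base <- random_atom_set(n_at, span = 2, seed = 31)
  # random walk of the molecule center plus 5 injected box jumps
  true_path <- matrix(0, nf, 3)
  for (f in 2:nf) true_path[f, ] <- true_path[f - 1, ] + rnorm(3, sd = 0.6)
  jumps <- matrix(0, nf, 3)
  for (j in sample(2:nf, 5))
    jumps[j:nf, ] <- sweep(jumps[j:nf, , drop = FALSE], 2,
                           box * sample(c(-1, 1), 3, TRUE) * rbinom(3, 1, 0.7),
                           "+")
  arr <- array(0, dim = c(n_at, 3, nf))
  for (f in 1:nf)
    arr[, , f] <- sweep(coords(base), 2, true_path[f, ] + jumps[f, ], "+")
  fixed <- unwrap_periodic(ensemble(base, arr), box)
  # oracle: continuous positions are base + true walk (no jumps)
  for (f in 1:nf)
    expect_equal(fixed$coords[, , f],
                 sweep(coords(base), 2, true_path[f, ], "+"),
                 tolerance = 1e-9)
})

test_that("best-fit r.m.s.d. vanishes for rigidly moved copies", {
  ref <- random_atom_set(18, span = 6, seed = 32)
  expect_equal(as.numeric(best_fit_rmsd(ref, ref)), 0)
  moved <- rotate_coordinates(ref, c(2, -1, 1), 73)
  coords(moved) <- sweep(coords(moved), 2, c(12, -5, 40), "+")
  expect_lt(as.numeric(best_fit_rmsd(moved, ref)), 1e-9)
})

test_that("best-fit r.m.s.d. agrees with quaternion and bio3d oracles", {
  set.seed(33)
  ref <- random_atom_set(20, span = 6, seed = 34)
  snap <- ref
  coords(snap) <- coords(ref) + matrix(rnorm(60, sd = 0.8), 20, 3)
  got <- as.numeric(best_fit_rmsd(snap, ref))
  expect_equal(got, oracle_rmsd(coords(snap), coords(ref)), tolerance = 1e-9)
  # cross-check against bio3d's least-squares fit
  xx <- matrix(t(coords(ref)), nrow = 1)
  yy <- matrix(t(coords(snap)), nrow = 1)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xx, mobile = yy))
  expect_equal(got, sqrt(mean(colSums(matrix((fitted - xx)^2, nrow = 3)))),
               tolerance = 1e-6)
  # one displaced atom among n after re-fit still matches the oracle
  snap2 <- ref
  cc <- coords(ref); cc[7, ] <- cc[7, ] + c(2, 0, 0)
  coords(snap2) <- cc
  expect_equal(as.numeric(best_fit_rmsd(snap2, ref)),
               oracle_rmsd(cc, coords(ref)), tolerance = 1e-9)
})

test_that("lattice r.m.s.d. keeps rotations and exceeds the best fit", {
  ref <- random_atom_set(16, span = 8, seed = 35)
  expect_equal(lattice_rmsd(ref, ref), 0)
  shifted <- ref
  coords(shifted) <- sweep(coords(ref), 2, c(5, 5, 5), "+")
  expect_equal(lattice_rmsd(shifted, ref), 0, tolerance = 1e-12)
  rot <- rotate_coordinates(ref, c(0, 1, 1), 25)
  expect_gt(lattice_rmsd(rot, ref), as.numeric(best_fit_rmsd(rot, ref)))
  expect_gt(lattice_rmsd(rot, ref), 0.1)
})

test_that("lattice r.m.s.d. >= best-fit r.m.s.d. on every frame", {
  base <- random_atom_set(12, span = 5, seed = 36)
  ens <- make_gaussian_ensemble(base, 0.5, 8, seed = 37)
  for (f in seq_len(n_frames(ens))) {
    fr <- ensemble_frame(ens, f)
    expect_gte(lattice_rmsd(fr, base),
               attr(best_fit_rmsd(fr, base), "mean") - 1e-12)
  }
})

test_that("r.m.s.f. is zero for static ensembles and converges to sigma*sqrt(3)", {
  base <- random_atom_set(50, span = 10, seed = 38)
  static <- make_gaussian_ensemble(base, 0, 5, seed = 39)
  expect_equal(rmsf(static, base, mode = "lattice"), rep(0, 50))
  sigma <- 0.4
  ens <- make_gaussian_ensemble(base, sigma, 1000, seed = 40)
  r <- rmsf(ens, base, mode = "lattice")
  expect_equal(mean(r), sigma * sqrt(3), tolerance = 0.05)
  expect_error(rmsf(make_gaussian_ensemble(base, 0.1, 1, seed = 1), base),
               "2 frames")
})

test_that("best-fit r.m.s.f. is invariant under a global rotation", {
  base <- random_atom_set(15, span = 5, seed = 41)
  ens <- make_gaussian_ensemble(base, 0.3, 40, seed = 42)
  rotated <- ens
  rr <- rotation_about_axis(c(1, 1, 1), 65)
  for (f in seq_len(n_frames(ens)))
    rotated$coords[, , f] <- ens$coords[, , f] %*% t(rr)
  expect_equal(rmsf(rotated, base, mode = "best_fit"),
               rmsf(ens, base, mode = "best_fit"), tolerance = 1e-6)
})

test_that("B factors follow B = (8 pi^2 / 3) rmsf^2 exactly", {
  expect_equal(b_from_rmsf(0), 0)
  expect_equal(b_from_rmsf(1), 8 * pi^2 / 3)
  r <- c(0.2, 0.7, 1.3)
  expect_equal(rmsf_from_b(b_from_rmsf(r)), r, tolerance = 1e-12)
  expect_error(b_from_rmsf(-0.1), "negative")
})

test_that("a Gaussian ensemble ties rmsf-derived B to its generator", {
  base <- random_atom_set(40, span = 12, seed = 43)
  sigma <- 0.3
  ens <- make_gaussian_ensemble(base, sigma, 256, seed = 44)
  b <- b_from_rmsf(mean(rmsf(ens, base, mode = "lattice")))
  expect_equal(b, 8 * pi^2 * sigma^2, tolerance = 0.1)
})

test_that("B-profile correlation is exact on affine and mirrored profiles", {
  p <- c(10, 14, 9, 30, 22, 17)
  expect_equal(b_profile_correlation(p, 2 * p + 3), 1)
  expect_equal(b_profile_correlation(p, -p), -1)
  set.seed(45)
  a <- runif(50); b <- runif(50)
  # two-pass textbook oracle
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(b_profile_correlation(a, b), oracle, tolerance = 1e-12)
  expect_error(b_profile_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(b_profile_correlation(1:2, 1:3), "length")
})

test_that("the hydrogen-bond truth table holds", {
  crit <- hbond_criteria()           # 3.5 A, 150 degrees
  d <- c(0, 0, 0); h <- c(1, 0, 0)
  expect_true(hbond(d, h, c(2.8, 0, 0), crit))          # 2.8 A, 180 deg
  expect_false(hbond(d, h, c(3.6, 0, 0), crit))         # distance fails
  # 140-degree geometry at 2.58 A: angle fails
  a140 <- h + 2.062 * c(cos(40 * pi / 180), sin(40 * pi / 180), 0)
  expect_lt(sqrt(sum((d - a140)^2)), 3.5)
  expect_false(hbond(d, h, a140, crit))
  expect_error(hbond(d, d, c(2, 0, 0), crit), "coincident")
})

test_that("water matching counts shared hydrogen-bond partners", {
  protein <- data.frame(
    element = c("O", "N", "O", "N"), name = c("O", "N", "OG", "ND2"),
    resname = c("GLY", "ALA", "SER", "ASN"), resno = 1:4, chain = "A",
    mol = 1L, x = c(0, 10, 20, 30), y = 0, z = 0, occ = 1, b = 0)
  water <- function(mol, resno, x, y = 0, z = 0)
    data.frame(element = "O", name = "O", resname = "HOH", resno = resno,
               chain = "W", mol = mol, x = x, y = y, z = z, occ = 1, b = 0)
  a <- atom_set(rbind(protein,
                      water(2L, 11, 2.8),          # partner GLY O
                      water(3L, 12, 12.9),         # partner ALA N
                      water(4L, 13, 22.8),         # partner SER OG
                      water(5L, 14, 50)))          # vacuum
  # identical structures: every H-bonded water matches itself
  self <- match_ordered_waters(a, a)
  expect_equal(self$matched, 3L)
  # displaced waters in B: only the first two keep their partners
  b <- atom_set(rbind(protein,
                      water(2L, 11, 3.1, 0.5),     # still GLY O
                      water(3L, 12, 12.7, -0.4),   # still ALA N
                      water(4L, 13, 55),           # vacuum
                      water(5L, 14, 60)))          # vacuum
  res <- match_ordered_waters(a, b)
  expect_equal(res$matched, 2L)
  expect_true(res$hydrogens_placed)
  # all waters displaced into vacuum: nothing matches
  c_ <- atom_set(rbind(protein, water(2L, 11, 50), water(3L, 12, 60),
                       water(4L, 13, 70), water(5L, 14, 80)))
  expect_equal(match_ordered_waters(a, c_)$matched, 0L)
})

test_that("per-residue B profiles average the requested selection", {
  x <- atom_set(data.frame(
    element = c("C", "C", "C", "C", "C"),
    name = c("CA", "CB", "CG", "CA", "CB"),
    resname = "LEU", resno = c(1, 1, 1, 2, 2), chain = "A", mol = 1L,
    x = 1:5, y = 0, z = 0, occ = 1, b = c(10, 20, 30, 40, 50)))
  ca <- b_profile(x, "calpha")
  expect_equal(ca$b, c(10, 40))
  sc <- b_profile(x, "sidechain_heavy")
  expect_equal(sc$b, c(25, 50))
})
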