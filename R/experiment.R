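# The oscillation-sampling experiment: how the merging statistic degrades
# when the angular sub-step used to build each oscillation frame is made
# coarser.  At full experimental scale this is measured on a solvated
# 125-unit supercell with an external integration program; at desk scale
# the same physics is probed on a soft-edged toy crystal with the
# package's own predictor, integrator and merger, and only the monotone
# trend across sub-steps is comparable, never the magnitudes.

#' Drop reflections whose spots collide on the detector
#'
#' Marks every pair of predicted reflections in the same frame whose
#' centers lie closer than `min_sep` pixels (Chebyshev distance); both
#' members of each colliding pair are removed — the summation integrator
#' has no profile model to deconvolve overlapped spots.
#'
#' @param table reflection table from [predict_reflections()].
#' @param min_sep minimum center-to-center separation, pixels.
#' @return the filtered table.
#' @export
reject_overlaps <- function(table, min_sep = 18) {
  clash <- rep(FALSE, nrow(table))
  for (fi in unique(table$frame)) {
    ix <- which(table$frame == fi)
    if (length(ix) < 2) next
    fx <- table$px_fast[ix]; fy <- table$px_slow[ix]
    for (a in seq_along(ix)) {
      sep <- pmax(abs(fx - fx[a]), abs(fy - fy[a]))
      hit <- which(sep < min_sep)
      if (length(hit) > 1) clash[ix[hit]] <- TRUE
    }
  }
  table[!clash, , drop = FALSE]
}

#' Oscillation-sampling (Delta-Omega) merging experiment
#'
#' Simulates rotation series of a static, ideally symmetric toy crystal
#' at several angular sub-steps, integrates the predicted Bragg spots on
#' the simulated photographs, applies the rotation-method Lorentz
#' correction (integrated intensity times crossing speed), merges
#' symmetry equivalents and reports R_merge per sub-step. Coarse
#' sub-steps sample each reflection's rocking curve at essentially one
#' arbitrary offset, so symmetry equivalents disagree wildly; fine
#' sub-steps approximate the full rocking integral and equivalents
#' converge — R_merge decreases as the sub-step is refined.
#'
#' The crystal is a point lattice with a Gaussian occupancy envelope
#' (soft-edged crystal: Gaussian spots and rocking curves, no
#' shape-transform tails). Reflections are filtered the way standard
#' data-reduction programs do before merging: grazing Ewald passages
#' (`rel_speed < min_rel_speed`), spot collisions, frame-boundary
#' partials and raster-edge spots are rejected.
#'
#' @param substeps sub-step widths in degrees, each dividing
#'   `frame_width` (default: frame width, /10, /100).
#' @param frame_width,total_range oscillation protocol, degrees.
#' @param cell_edge cubic lattice constant of the toy crystal, angstrom.
#' @param n_cells lattice repeats per axis.
#' @param envelope_sigma Gaussian crystal-envelope width, angstrom.
#' @param d_range resolution shell analysed (angstrom, c(min, max)).
#' @param min_rel_speed grazing-passage cutoff on the dimensionless
#'   crossing obliquity.
#' @param box,bg_annulus integration window (see [integrate_spot()]).
#' @param geom detector geometry (default: 192 x 192 px of 0.5 mm at
#'   90 mm, 1.54 angstrom).
#' @param orientation crystal orientation (default: a generic rotation
#'   avoiding axis-aligned degeneracies).
#' @return data frame with one row per sub-step: `substep`,
#'   `n_reflections`, `n_groups` (multiplicity >= 2) and `r_merge`.
#' @export
delta_omega_experiment <- function(substeps = c(30, 3, 0.3),
                                   frame_width = 30, total_range = 90,
                                   cell_edge = 10, n_cells = 12,
                                   envelope_sigma = 30,
                                   d_range = c(2.5, 3.8),
                                   min_rel_speed = 0.2,
                                   box = 5L, bg_annulus = 8L,
                                   geom = NULL, orientation = NULL) {
  if (is.null(geom))
    geom <- detector_geometry(1.54, 90, 0.5, c(192, 192), c(95.5, 95.5))
  if (is.null(orientation))
    orientation <- orientation_matrix(rotation_about_axis(c(1, 2, 3), 15))
  cell <- unit_cell(cell_edge)
  sg <- space_group("P43212")   # 422 point symmetry for merging
  lat <- make_point_lattice(n_cells, n_cells, n_cells, cell_edge,
                            envelope_sigma = envelope_sigma)
  # predict down to the detector's resolution limit so the collision
  # filter sees every spot present on the images, not just the shell
  d_det <- 1 / (2 * max(momentum_transfer(rbind(
    c(0, 0), c(geom$raster[1] - 1, 0), c(0, geom$raster[2] - 1),
    geom$raster - 1), geom)))
  edge_margin <- bg_annulus + 1L
  out <- data.frame(substep = substeps, n_reflections = NA_integer_,
                    n_groups = NA_integer_, r_merge = NA_real_)
  for (si in seq_along(substeps)) {
    series <- rotation_series(0, frame_width, substeps[si], total_range)
    full <- predict_reflections(cell, orientation, series, geom,
                                d_min = max(d_det, 0.55 * geom$wavelength),
                                boundary_tol = 3.0)
    full <- reject_overlaps(full, min_sep = 18)
    tab <- full[!full$partial &
                  full$rel_speed >= min_rel_speed &
                  full$d >= d_range[1] & full$d <= d_range[2] &
                  full$px_fast >= edge_margin &
                  full$px_fast <= geom$raster[1] - 1 - edge_margin &
                  full$px_slow >= edge_margin &
                  full$px_slow <= geom$raster[2] - 1 - edge_margin, ]
    photos <- vector("list", series$n_frames)
    for (fi in unique(tab$frame)) {
      sub <- tab[tab$frame == fi, ]
      w <- bg_annulus + 1L
      pxl <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        fx <- round(sub$px_fast[i]); fy <- round(sub$px_slow[i])
        as.matrix(expand.grid((fx - w):(fx + w), (fy - w):(fy + w)))
      }))
      pxl <- unique(pxl)
      pxl <- pxl[pxl[, 1] >= 0 & pxl[, 1] <= geom$raster[1] - 1 &
                   pxl[, 2] >= 0 & pxl[, 2] <= geom$raster[2] - 1, ,
                 drop = FALSE]
      photos[[fi + 1]] <- simulate_frame(lat, geom, series, orientation, fi,
                                         pixels = pxl)
    }
    tab <- integrate_reflections(photos, tab, box = box,
                                 bg_annulus = bg_annulus)
    tab <- tab[!tab$partial, ]
    tab$intensity <- tab$intensity * tab$lorentz_speed   # Lorentz correction
    keys <- .canonical_keys(as.matrix(tab[, c("h", "k", "l")]), sg, TRUE)
    out$n_reflections[si] <- nrow(tab)
    out$n_groups[si] <- sum(table(keys) >= 2)
    out$r_merge[si] <- as.numeric(r_merge(tab, sg))
  }
  out
}
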