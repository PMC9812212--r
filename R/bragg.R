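# Desk-scale analogue of the external integration step: predict Bragg
# reflections from the Ewald condition, integrate spots by summation with
# a median background, merge symmetry equivalents and compute R_merge.

# reciprocal-basis matrix: columns are a*, b*, c* in 1/angstrom
# (crystallographic convention, no 2 pi), so q = Brec %*% hkl.
reciprocal_matrix <- function(cell) {
  t(solve(orthogonalization_matrix(cell)))
}

#' Predict Bragg reflections crossing the Ewald sphere
#'
#' For every index triple with `d >= d_min`, solves in closed form for
#' the rotation angles (about lab x) at which the reciprocal-lattice
#' vector satisfies the elastic Ewald condition `|k + q| = 1/lambda`,
#' maps each crossing to a detector pixel, keeps in-raster hits, and
#' assigns the reflection to the oscillation frame containing the
#' crossing angle. A crossing closer than `boundary_tol` degrees to a
#' frame boundary is flagged partial rather than split.
#'
#' @param cell a [unit_cell()].
#' @param orientation an [orientation_matrix()].
#' @param series a [rotation_series()].
#' @param geom a [detector_geometry()].
#' @param d_min resolution cutoff, angstrom; must exceed `lambda / 2`.
#' @param boundary_tol frame-boundary tolerance, degrees.
#' @return data frame (`reflection table`): `h, k, l, frame, omega,
#'   px_fast, px_slow, d, lorentz_speed, rel_speed, partial`.
#'   `lorentz_speed` is the Ewald crossing speed (inverse angstrom per
#'   radian); its reciprocal is the rotation-method Lorentz factor.
#'   `rel_speed = lorentz_speed * d` is the dimensionless obliquity of
#'   the crossing (near 0 for grazing passages).
#' @export
predict_reflections <- function(cell, orientation, series, geom, d_min,
                                boundary_tol = 0.01) {
  lam <- geom$wavelength
  if (d_min <= lam / 2)
    stop("predict_reflections: d_min must exceed lambda / 2 (Bragg limit)")
  brec <- reciprocal_matrix(cell)
  hmax <- ceiling(cell$a / d_min)
  kmax <- ceiling(cell$b / d_min)
  lmax <- ceiling(cell$c / d_min)
  hkl <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  q0 <- hkl %*% t(brec) %*% t(unclass(orientation))  # lab frame at omega = 0
  qlen <- sqrt(rowSums(q0^2))
  d <- 1 / qlen
  keep <- d >= d_min
  hkl <- hkl[keep, , drop = FALSE]; q0 <- q0[keep, , drop = FALSE]
  qlen <- qlen[keep]; d <- d[keep]
  # Ewald condition after rotation about x:  q_z(omega) = -lambda |q|^2 / 2,
  # with q_z(omega) = q_y0 * (-sin omega)?  Using R_x(omega):
  #   q_y(omega) = q_y0 cos - q_z0 sin ... z-row: q_z = q_y0 sin + q_z0 cos
  a_co <- q0[, 3]; b_si <- q0[, 2]
  rhs <- -lam * qlen^2 / 2
  amp <- sqrt(a_co^2 + b_si^2)
  phi <- atan2(b_si, a_co)
  ratio <- rhs / amp
  sol <- which(amp > 0 & abs(ratio) <= 1)
  deg <- 180 / pi
  rows <- list(); ri <- 0L
  for (i in sol) {
    base <- acos(ratio[i])
    for (sgn in c(1, -1)) {
      omega <- (phi[i] + sgn * base) * deg
      omega <- ((omega - series$start) %% 360) + series$start
      if (omega >= series$start + series$total_range) next
      rot <- rotation_about_axis(c(1, 0, 0), omega)
      q <- as.vector(rot %*% q0[i, ])
      kp <- c(0, 0, 1 / lam) + q           # scattered wavevector
      if (kp[3] <= 0) next
      # pixel center of the scattered ray
      fx <- geom$beam_center[1] + (geom$distance * kp[1] / kp[3]) / geom$pixel_mm
      fy <- geom$beam_center[2] + (geom$distance * kp[2] / kp[3]) / geom$pixel_mm
      if (fx < 0 || fx > geom$raster[1] - 1 || fy < 0 || fy > geom$raster[2] - 1)
        next
      fr <- floor((omega - series$start) / series$frame_width)
      off <- (omega - series$start) %% series$frame_width
      part <- off < boundary_tol || series$frame_width - off < boundary_tol
      # Ewald crossing speed |d q_z / d omega| (A^-1 per radian): the
      # rotation-method Lorentz factor is its reciprocal
      wrad <- omega * pi / 180
      speed <- abs(b_si[i] * cos(wrad) - a_co[i] * sin(wrad))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(h = hkl[i, 1], k = hkl[i, 2], l = hkl[i, 3],
                               frame = as.integer(fr), omega = omega,
                               px_fast = fx, px_slow = fy, d = d[i],
                               lorentz_speed = speed,
                               rel_speed = speed * d[i],
                               partial = part)
    }
  }
  if (!ri) {
    return(data.frame(h = integer(0), k = integer(0), l = integer(0),
                      frame = integer(0), omega = numeric(0),
                      px_fast = numeric(0), px_slow = numeric(0),
                      d = numeric(0), lorentz_speed = numeric(0),
                      rel_speed = numeric(0), partial = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrate one spot by box summation with median background
#'
#' `intensity = sum(box) - n_box * median(annulus)`; the background
#' estimate is the annulus median. A window clipped by the raster or
#' touching masked pixels sets the partiality flag.
#'
#' @param photo a [photograph()].
#' @param pos spot center in (fast, slow) pixels (rounded to the nearest
#'   pixel center).
#' @param box half-width of the summation box, pixels.
#' @param bg_annulus outer half-width of the background annulus, pixels
#'   (annulus = Chebyshev shell between `box` and `bg_annulus`).
#' @return list with `intensity`, `background`, `partial`.
#' @export
integrate_spot <- function(photo, pos, box = 3L, bg_annulus = 5L) {
  stopifnot(bg_annulus > box)
  n1 <- nrow(photo$intensity); n2 <- ncol(photo$intensity)
  c1 <- round(pos[1]) + 1L; c2 <- round(pos[2]) + 1L   # 1-based center
  w1 <- (c1 - bg_annulus):(c1 + bg_annulus)
  w2 <- (c2 - bg_annulus):(c2 + bg_annulus)
  clipped <- any(w1 < 1 | w1 > n1 | w2 < 1 | w2 > n2)
  w1 <- w1[w1 >= 1 & w1 <= n1]; w2 <- w2[w2 >= 1 & w2 <= n2]
  sub <- photo$intensity[w1, w2, drop = FALSE]
  subm <- photo$mask[w1, w2, drop = FALSE]
  di <- abs(w1 - c1); dj <- abs(w2 - c2)
  cheb <- outer(di, dj, pmax)
  in_box <- cheb <= box
  in_ann <- cheb > box & cheb <= bg_annulus
  partial <- clipped || any(!subm[in_box | in_ann])
  bg <- stats::median(sub[in_ann & subm])
  if (!is.finite(bg)) bg <- 0
  n_box_full <- (2 * box + 1)^2
  intensity <- sum(sub[in_box & subm]) - n_box_full * bg
  list(intensity = intensity, background = bg, partial = partial)
}

#' Integrate all predicted reflections on a photograph series
#'
#' Convenience wrapper joining [predict_reflections()] output to
#' [integrate_spot()] results, one photograph per frame.
#'
#' @param photos list of [photograph()]s indexed by frame (0-based frame
#'   `i` at `photos[[i + 1]]`).
#' @param table reflection table from [predict_reflections()].
#' @inheritParams integrate_spot
#' @return the table with `intensity`, `background` and updated `partial`
#'   columns.
#' @export
integrate_reflections <- function(photos, table, box = 3L, bg_annulus = 5L) {
  n <- nrow(table)
  ints <- numeric(n); bgs <- numeric(n); part <- logical(n)
  for (i in seq_len(n)) {
    ph <- photos[[table$frame[i] + 1L]]
    r <- integrate_spot(ph, c(table$px_fast[i], table$px_slow[i]),
                        box = box, bg_annulus = bg_annulus)
    ints[i] <- r$intensity; bgs[i] <- r$background
    part[i] <- table$partial[i] || r$partial
  }
  table$intensity <- ints
  table$background <- bgs
  table$partial <- part
  table
}

#' Symmetry-equivalent reflections
#'
#' Orbit of an index triple under the point group derived from the
#' rotation parts of the space-group operators, optionally united with
#' the Friedel mates. The canonical representative of an orbit is its
#' lexicographic maximum (compared on h, then k, then l).
#'
#' @param hkl integer 3-vector.
#' @param sg a [space_group()].
#' @param friedel include Friedel mates (default TRUE).
#' @return integer matrix, one orbit member per row; the canonical
#'   representative is given by `attr(, "canonical")`.
#' @export
symmetry_equivalents <- function(hkl, sg, friedel = TRUE) {
  hkl <- as.integer(round(hkl))
  orbit <- t(vapply(sg$ops, function(op) {
    as.integer(round(as.vector(hkl %*% op$rot)))
  }, integer(3)))
  if (friedel) orbit <- rbind(orbit, -orbit)
  orbit <- unique(orbit)
  ord <- order(orbit[, 1], orbit[, 2], orbit[, 3], decreasing = TRUE)
  orbit <- orbit[ord, , drop = FALSE]
  attr(orbit, "canonical") <- orbit[1, ]
  orbit
}

# canonical key for each row of an hkl matrix
.canonical_keys <- function(hkl_mat, sg, friedel) {
  apply(hkl_mat, 1, function(v) {
    paste(attr(symmetry_equivalents(v, sg, friedel), "canonical"),
          collapse = ",")
  })
}

#' Merging R factor over symmetry-equivalent reflections
#'
#' \deqn{R_{merge} = \frac{\sum_h \sum_i |I_{h,i} - \langle I_h \rangle|}
#' {\sum_h \sum_i I_{h,i}},}
#' summed over groups of symmetry-equivalent observations with
#' multiplicity >= 2, keyed by the canonical equivalent. Negative
#' integrated intensities are kept so the statistic reflects integration
#' noise honestly; groups whose intensity sum is non-positive are dropped
#' (their count is reported in the `dropped_groups` attribute).
#'
#' @param table reflection table with columns `h, k, l, intensity`.
#' @param sg a [space_group()].
#' @param friedel merge Friedel mates (default TRUE).
#' @return the R_merge statistic (non-negative scalar).
#' @export
r_merge <- function(table, sg, friedel = TRUE) {
  stopifnot(all(c("h", "k", "l", "intensity") %in% names(table)))
  keys <- .canonical_keys(as.matrix(table[, c("h", "k", "l")]), sg, friedel)
  groups <- split(table$intensity, keys)
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups))
    stop("r_merge: no symmetry groups with multiplicity >= 2")
  sums <- vapply(groups, sum, 0)
  dropped <- sum(sums <= 0)
  groups <- groups[sums > 0]
  if (!length(groups))
    stop("r_merge: all multiplicity >= 2 groups have non-positive sums")
  num <- sum(vapply(groups, function(g) sum(abs(g - mean(g))), 0))
  den <- sum(vapply(groups, sum, 0))
  structure(num / den, dropped_groups = dropped)
}

#' Write a reflection table as CSV
#'
#' @param table reflection table.
#' @param path output path.
#' @export
write_reflection_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
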