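# FFT-based photograph engine: grid the electron density of each snapshot
# (Gaussian spreading consistent with the form-factor parameterization),
# Fourier-transform once per snapshot, then interpolate the transform onto
# the Ewald sphere for every rotation sub-step.  By default snapshots are
# accumulated by intensity (per-snapshot |F|^2), mirroring the direct
# engine; amplitude-level density averaging is available as an option and
# differs for dynamic ensembles (it suppresses diffuse scattering).

# round up to a 2,3,5-smooth integer for fast mixed-radix FFTs
.nice_grid_size <- function(n) {
  n <- max(4L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# density of one snapshot on a regular grid with per-axis sizes ng and
# spacing h, box origin at `origin` (angstrom).  b_blur is the extra
# isotropic B (angstrom^2) folded into every Gaussian term (and standing
# in for the constant term) to keep the density band-limited; it is
# divided back out at interpolation time.
.grid_density <- function(snapshot, ng, h, origin, b_blur) {
  rho <- array(0, dim = ng)
  xyz <- coords(snapshot)
  tab <- scattering_table()
  for (el in unique(snapshot$element)) {
    cf <- tab[toupper(el), ]
    if (is.null(cf) || is.na(cf$a1))
      stop("unknown element in scattering table: ", el)
    amp <- as.numeric(cf[paste0("a", 1:4)])
    bet <- as.numeric(cf[paste0("b", 1:4)])
    amp <- c(amp, as.numeric(cf$c)); bet <- c(bet, 0)
    aa <- (bet + b_blur) / 4                   # exp(-a |q|^2) widths
    height <- amp * (pi / aa)^1.5              # real-space peak heights
    decay <- pi^2 / aa                         # exp(-decay r^2)
    rcut <- sqrt(30 / min(decay))              # tail cutoff
    nc <- ceiling(rcut / h)
    off <- (-nc):nc                            # local cube offsets
    idx <- which(snapshot$element == el)
    for (j in idx) {
      r0 <- xyz[j, ]
      g0 <- round((r0 - origin) / h)           # nearest grid node
      gx <- g0[1] + off; gy <- g0[2] + off; gz <- g0[3] + off
      keep_x <- gx >= 0 & gx < ng[1]
      keep_y <- gy >= 0 & gy < ng[2]
      keep_z <- gz >= 0 & gz < ng[3]
      gx <- gx[keep_x]; gy <- gy[keep_y]; gz <- gz[keep_z]
      dx <- origin[1] + gx * h - r0[1]
      dy <- origin[2] + gy * h - r0[2]
      dz <- origin[3] + gz * h - r0[3]
      r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
      dens <- array(0, dim = dim(r2))
      for (m in seq_along(height)) {
        v <- height[m] * exp(-decay[m] * r2)
        dens <- dens + v
      }
      w <- snapshot$occ[j]
      rho[gx + 1, gy + 1, gz + 1] <- rho[gx + 1, gy + 1, gz + 1] + w * dens
    }
  }
  rho
}

# Structure factor of a density given on real grid points
# x_g = origin + g h:  F(q_m) = h^3 sum_g rho_g exp(2 pi i q_m . x_g) at
# q_m = m / L.  The inverse DFT supplies sum_g rho_g exp(2 pi i m g / n);
# referencing phases to the box CENTER (not the corner) makes the stored
# transform smooth in m — it then varies on the scale of the inverse
# crystal extent and interpolates accurately.  Relative to the center,
# x_g - center = (g - n/2) h, so the centered transform is the DFT times
# the checkerboard factor (-1)^(mx+my+mz).  The remaining global phase
# exp(2 pi i q . center) has unit modulus and never enters |F|^2.
.fft_structure_factor <- function(rho, h) {
  ng <- dim(rho)
  fg <- stats::fft(rho, inverse = TRUE) * h^3
  chk <- outer(outer((-1)^(seq_len(ng[1]) - 1), (-1)^(seq_len(ng[2]) - 1)),
               (-1)^(seq_len(ng[3]) - 1))
  fg * chk
}

# Keys cubic (Catmull-Rom) interpolation weights for fractional offset t
.cubic_weights <- function(t) {
  # nodes at -1, 0, 1, 2 relative to the base index
  cbind(((-0.5 * t + 1) * t - 0.5) * t,
        (1.5 * t - 2.5) * t * t + 1,
        ((-1.5 * t + 2) * t + 0.5) * t,
        (0.5 * t - 0.5) * t * t)
}

# interpolate complex F at continuous frequency indices u (n x 3), with
# periodic wrap; u must stay 2 cells clear of the Nyquist fold
.interp_f <- function(fgrid, u) {
  ng <- dim(fgrid)
  base <- floor(u)
  tfrac <- u - base
  wx <- .cubic_weights(tfrac[, 1])
  wy <- .cubic_weights(tfrac[, 2])
  wz <- .cubic_weights(tfrac[, 3])
  out <- complex(real = numeric(nrow(u)), imaginary = numeric(nrow(u)))
  for (ix in 0:3) {
    gx <- (base[, 1] + ix - 1L) %% ng[1]
    for (iy in 0:3) {
      gy <- (base[, 2] + iy - 1L) %% ng[2]
      wxy <- wx[, ix + 1] * wy[, iy + 1]
      for (iz in 0:3) {
        gz <- (base[, 3] + iz - 1L) %% ng[3]
        lin <- 1L + gx + ng[1] * (gy + ng[2] * gz)
        out <- out + (wxy * wz[, iz + 1]) * fgrid[lin]
      }
    }
  }
  out
}

#' Simulate one oscillation frame through the FFT engine
#'
#' Cross-validation path for [simulate_frame()]: per snapshot, the
#' electron density is spread onto a padded cubic grid with Gaussians
#' matching the form-factor parameterization (sharpened back at lookup by
#' the band-limiting blur), Fourier-transformed once, and interpolated
#' onto the Ewald sphere at every sub-step; sub-steps and snapshots
#' accumulate by intensity exactly as in the direct engine.
#'
#' @inheritParams simulate_frame
#' @param grid_spacing real-space grid spacing, angstrom; must satisfy
#'   `grid_spacing <= d_min / 3` for the finest resolution probed.
#' @param padding box-edge multiple of the snapshot extent (reciprocal
#'   oversampling of the crystal shape transform).
#' @param b_blur band-limiting blur in angstrom^2; default
#'   `8 * pi^2 * (0.9 * grid_spacing)^2`.
#' @param average_amplitude if TRUE, snapshot densities are averaged
#'   before squaring (amplitude-level accumulation). This differs from the
#'   intensity-level default for dynamic ensembles: it suppresses diffuse
#'   scattering.
#' @return a [photograph()] with `engine = "fft"`.
#' @export
fft_photograph <- function(ens, geom, series,
                           orientation = orientation_matrix(),
                           frame_index = 0L, grid_spacing = 0.8,
                           padding = 4, pixels = NULL, mask = NULL,
                           b_blur = NULL, average_amplitude = FALSE) {
  ens <- as_ensemble(ens)
  plan <- frame_plan(series)
  if (frame_index < 0 || frame_index >= length(plan))
    stop("fft_photograph: frame index outside the frame plan")
  angles <- plan[[frame_index + 1]]$angles
  px <- .resolve_pixels(geom, pixels, mask)
  qlab <- pixel_q(px, geom)
  smax <- max(sqrt(rowSums(qlab^2))) / 2
  d_min <- 1 / (2 * smax)
  if (grid_spacing > d_min / 3)
    stop(sprintf(paste0("fft_photograph: grid too coarse for the requested ",
                        "resolution (implied d_min = %.3f A needs spacing ",
                        "<= %.3f A)"), d_min, d_min / 3))
  if (is.null(b_blur)) b_blur <- 8 * pi^2 * (0.9 * grid_spacing)^2
  # common box for all snapshots, centered on the ensemble
  all_lo <- c(Inf, Inf, Inf); all_hi <- -all_lo
  for (m in seq_len(n_frames(ens))) {
    cc <- ens$coords[, , m, drop = FALSE]
    dim(cc) <- dim(ens$coords)[1:2]
    all_lo <- pmin(all_lo, apply(cc, 2, min))
    all_hi <- pmax(all_hi, apply(cc, 2, max))
  }
  extent <- max(all_hi - all_lo)
  tail <- 5 * sqrt((max(scattering_table()$b4, 60) + b_blur) / 4) / pi
  edge <- padding * (extent + 2 * tail)
  n1 <- .nice_grid_size(edge / grid_spacing)
  ng <- c(n1, n1, n1)
  len <- ng * grid_spacing
  center <- (all_lo + all_hi) / 2
  origin <- center - len / 2
  acc <- numeric(nrow(px))
  famp <- NULL
  nsnap <- n_frames(ens)
  rots <- lapply(angles, function(a)
    rotation_about_axis(c(1, 0, 0), a) %*% unclass(orientation))
  for (m in seq_len(nsnap)) {
    rho <- .grid_density(ensemble_frame(ens, m), ng, grid_spacing, origin,
                         b_blur)
    fg <- .fft_structure_factor(rho, grid_spacing)
    if (average_amplitude) {
      if (is.null(famp)) famp <- fg / nsnap else famp <- famp + fg / nsnap
      next
    }
    for (rot in rots) {
      qcr <- qlab %*% rot
      u <- sweep(qcr, 2, len, "*")
      fv <- .interp_f(fg, u)
      fv <- fv * exp(b_blur * rowSums(qcr^2) / 4)   # undo the blur
      acc <- acc + Re(fv)^2 + Im(fv)^2
    }
  }
  if (average_amplitude) {
    for (rot in rots) {
      qcr <- qlab %*% rot
      u <- sweep(qcr, 2, len, "*")
      fv <- .interp_f(famp, u)
      fv <- fv * exp(b_blur * rowSums(qcr^2) / 4)
      acc <- acc + nsnap * (Re(fv)^2 + Im(fv)^2)
    }
  }
  .photo_from_values(acc, px, geom, frame_index, series, nsnap, "fft")
}
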