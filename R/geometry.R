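#' Detector and beam geometry
#'
#' The incident beam travels along lab +z with wavevector magnitude
#' `1/lambda` (cycles per angstrom); the flat detector is perpendicular to
#' the beam at the given crystal-to-detector distance. Pixel (0, 0) sits
#' at one corner, the fast axis is horizontal (lab x), indices are 0-based
#' and amplitudes are evaluated at pixel centers.
#'
#' @param wavelength X-ray wavelength, angstrom.
#' @param distance crystal-to-detector distance, mm.
#' @param pixel_mm pixel pitch, mm.
#' @param raster integer length-2: (n_fast, n_slow) pixels.
#' @param beam_center length-2: beam-center position in (fast, slow)
#'   pixel units; must lie inside the raster.
#' @return object of class `detector_geometry`.
#' @examples
#' detector_geometry(1.54, 45, 0.3, c(487, 407), c(243, 203))
#' @export
detector_geometry <- function(wavelength, distance, pixel_mm, raster,
                              beam_center = (raster - 1) / 2) {
  stopifnot(wavelength > 0, distance > 0, pixel_mm > 0,
            length(raster) == 2, all(raster >= 1),
            length(beam_center) == 2)
  if (any(beam_center < 0) || any(beam_center > raster - 1))
    stop("detector_geometry: beam center outside raster")
  structure(list(wavelength = wavelength, distance = distance,
                 pixel_mm = pixel_mm, raster = as.integer(raster),
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "<detector_geometry> lambda=%.4f A, distance=%.1f mm, pitch=%.3f mm, %dx%d px\n",
    x$wavelength, x$distance, x$pixel_mm, x$raster[1], x$raster[2]))
  invisible(x)
}

#' Rotation-series protocol
#'
#' The crystal rotates about the lab x axis. Each oscillation frame spans
#' `frame_width` degrees and is built from finer `substep` increments
#' (the reference protocol: 1 degree frames from ten 0.1 degree sub-steps,
#' 180 frames covering 180 degrees). Sub-step angles are placed at
#' sub-step midpoints within the frame.
#'
#' @param start start angle, degrees.
#' @param frame_width oscillation width of one frame, degrees; must be an
#'   integer multiple of `substep`.
#' @param substep angular sub-step (the Delta-Omega of the protocol),
#'   degrees.
#' @param total_range total rotation range, degrees; integer multiple of
#'   `frame_width`.
#' @return object of class `rotation_series`.
#' @examples
#' rotation_series(0, 1, 0.1, 180)   # 180 frames, 10 sub-steps each
#' @export
rotation_series <- function(start = 0, frame_width = 1, substep = 0.1,
                            total_range = 180) {
  stopifnot(frame_width > 0, substep > 0, total_range > 0)
  ratio <- frame_width / substep
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("rotation_series: frame_width must be an integer multiple of substep")
  nfr <- total_range / frame_width
  if (abs(nfr - round(nfr)) > 1e-9)
    stop("rotation_series: total_range must be an integer multiple of frame_width")
  structure(list(start = start, frame_width = frame_width, substep = substep,
                 total_range = total_range,
                 n_frames = as.integer(round(nfr)),
                 substeps_per_frame = as.integer(round(ratio))),
            class = "rotation_series")
}

#' @export
print.rotation_series <- function(x, ...) {
  cat(sprintf(
    "<rotation_series> %d frames x %.4g deg (substep %.4g deg), start %.4g deg\n",
    x$n_frames, x$frame_width, x$substep, x$start))
  invisible(x)
}

#' Validate an orientation matrix
#'
#' A proper rotation applied to all snapshot coordinates before the
#' rotation series begins (the crystal-orientation input; this package
#' does not attempt to determine it from data).
#'
#' @param m 3 x 3 matrix; orthogonal with determinant +1 within 1e-9.
#' @return the matrix, classed `orientation_matrix`.
#' @export
orientation_matrix <- function(m = diag(3)) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(3, 3)))
  if (max(abs(crossprod(m) - diag(3))) > 1e-9 || abs(det(m) - 1) > 1e-9)
    stop("orientation_matrix: not a proper rotation")
  structure(m, class = c("orientation_matrix", "matrix"))
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (normalized internally; zero axis is an error).
#' @param angle rotation angle, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation_about_axis: zero axis")
  u <- axis / n
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Rigidly rotate an atom set about the origin
#'
#' @param atoms an `atom_set`.
#' @param axis rotation axis (3-vector).
#' @param angle angle in degrees.
#' @export
rotate_coordinates <- function(atoms, axis, angle) {
  r <- rotation_about_axis(axis, angle)
  coords(atoms) <- coords(atoms) %*% t(r)
  atoms
}

# lab-frame pixel-center positions (mm) for 0-based pixel indices
.pixel_lab_mm <- function(px, geom) {
  px <- matrix(px, ncol = 2)
  cbind((px[, 1] - geom$beam_center[1]) * geom$pixel_mm,
        (px[, 2] - geom$beam_center[2]) * geom$pixel_mm,
        geom$distance)
}

.check_in_raster <- function(px, geom) {
  px <- matrix(px, ncol = 2)
  bad <- px[, 1] < 0 | px[, 1] > geom$raster[1] - 1 |
    px[, 2] < 0 | px[, 2] > geom$raster[2] - 1
  if (any(bad)) stop("pixel outside raster")
}

#' Scattered wavevector seen by a pixel
#'
#' Returns k' = (1/lambda) u, where u is the unit vector from the crystal
#' origin to the pixel center; elastic scattering, |k'| = |k| = 1/lambda.
#'
#' @param px pixel indices: length-2 vector or n x 2 matrix of (fast,
#'   slow), 0-based.
#' @param geom a [detector_geometry()].
#' @return n x 3 matrix of wavevectors in inverse angstrom.
#' @export
pixel_to_kprime <- function(px, geom) {
  .check_in_raster(px, geom)
  pos <- .pixel_lab_mm(px, geom)
  u <- pos / sqrt(rowSums(pos^2))
  u / geom$wavelength
}

#' Momentum transfer of a pixel
#'
#' `s = |k - k'| / 2`, identical to sin(theta)/lambda — the argument of
#' the atomic form factor.
#'
#' @inheritParams pixel_to_kprime
#' @return numeric vector of s values, inverse angstrom.
#' @export
momentum_transfer <- function(px, geom) {
  kp <- pixel_to_kprime(px, geom)
  k <- c(0, 0, 1 / geom$wavelength)
  q <- sweep(-kp, 2, k, "+")   # k - k'
  sqrt(rowSums(q^2)) / 2
}

# q = k - k' for a set of pixels, n x 3 (used by the engine; note the
# engine phase convention is exp(+2 pi i r . (k - k')))
pixel_q <- function(px, geom) {
  kp <- pixel_to_kprime(px, geom)
  k <- matrix(c(0, 0, 1 / geom$wavelength), nrow(kp), 3, byrow = TRUE)
  k - kp
}

#' Oscillation-frame plan of a rotation series
#'
#' One entry per frame, each holding the mid-point angles of its
#' sub-steps; frames tile the total range without overlap.
#'
#' @param series a [rotation_series()].
#' @return list of lists with elements `frame` (0-based index) and
#'   `angles` (degrees).
#' @examples
#' length(frame_plan(rotation_series(0, 1, 0.1, 180)))  # 180
#' @export
frame_plan <- function(series) {
  stopifnot(inherits(series, "rotation_series"))
  lapply(seq_len(series$n_frames) - 1L, function(fi) {
    f0 <- series$start + fi * series$frame_width
    sub <- seq_len(series$substeps_per_frame) - 1L
    list(frame = fi,
         angles = f0 + (sub + 0.5) * series$substep)
  })
}

#' All pixel indices of a raster
#'
#' @param geom a [detector_geometry()].
#' @return (n_fast * n_slow) x 2 integer matrix in fast-major order
#'   (fast index varies fastest), matching R's column-major raster layout.
#' @export
raster_pixels <- function(geom) {
  cbind(rep(seq_len(geom$raster[1]) - 1L, times = geom$raster[2]),
        rep(seq_len(geom$raster[2]) - 1L, each = geom$raster[1]))
}
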