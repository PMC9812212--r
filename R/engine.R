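#' Photograph objects
#'
#' A `photograph` is a real-valued intensity raster (arbitrary units) plus
#' provenance: frame index, angular interval, snapshot count and a pixel
#' validity mask (`TRUE` = simulated pixel; masked or unsimulated pixels
#' hold 0 and are flagged invalid).
#'
#' @param intensity n_fast x n_slow numeric matrix, non-negative, finite.
#' @param frame 0-based frame index.
#' @param angle_start,angle_width angular interval of the frame, degrees.
#' @param n_snapshots number of ensemble snapshots accumulated.
#' @param mask logical matrix of the same shape as `intensity`.
#' @param engine `"direct"` or `"fft"`.
#' @export
photograph <- function(intensity, frame = 0L, angle_start = 0,
                       angle_width = 1, n_snapshots = 1L,
                       mask = NULL, engine = "direct") {
  intensity <- as.matrix(intensity)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  stopifnot(all(dim(mask) == dim(intensity)))
  if (!all(is.finite(intensity)) || any(intensity < 0))
    stop("photograph: intensities must be finite and non-negative")
  structure(list(intensity = intensity, frame = as.integer(frame),
                 angle_start = angle_start, angle_width = angle_width,
                 n_snapshots = as.integer(n_snapshots), mask = mask,
                 engine = engine),
            class = "photograph")
}

#' @export
print.photograph <- function(x, ...) {
  cat(sprintf(
    "<photograph> frame %d [%g, %g) deg, %dx%d px, %d snapshot(s), engine=%s\n",
    x$frame, x$angle_start, x$angle_start + x$angle_width,
    nrow(x$intensity), ncol(x$intensity), x$n_snapshots, x$engine))
  invisible(x)
}

as_ensemble <- function(x) {
  if (inherits(x, "ensemble")) x
  else if (inherits(x, "atom_set")) ensemble(x)
  else stop("expected an atom_set or ensemble")
}

#' Phase of the wavelet scattered by an atom
#'
#' The phase difference of light diffracted at position `r`, relative to
#' the optical path through the origin: `delta = 2 pi r . (k - k')`, with
#' wavevectors in the `|k| = 1/lambda` (cycles per angstrom) convention.
#'
#' @param r position, angstrom (3-vector or n x 3 matrix).
#' @param k incident wavevector (3-vector, inverse angstrom).
#' @param kprime scattered wavevector (3-vector).
#' @return phase(s) in radians.
#' @export
wavelet_phase <- function(r, k, kprime) {
  r <- matrix(r, ncol = 3)
  2 * pi * as.vector(r %*% (k - kprime))
}

# Complex amplitude sum over atoms for a block of q vectors (nq x 3).
# coords: n x 3; weights multiply each atom (occupancy); f_by_elem: element
# x nq matrix of form factors at the block's s values; b: per-atom B used
# only when use_b is TRUE.
.amplitude_block <- function(xyz, elements, occ, b, q, f_by_elem, use_b) {
  nq <- nrow(q)
  acc <- complex(real = numeric(nq), imaginary = numeric(nq))
  s2 <- NULL
  if (use_b) s2 <- rowSums(q^2) / 4
  for (el in rownames(f_by_elem)) {
    idx <- which(elements == el)
    if (!length(idx)) next
    ph <- xyz[idx, , drop = FALSE] %*% t(q)       # n_el x nq
    w <- exp(2i * pi * ph)
    if (use_b && any(b[idx] > 0)) {
      damp <- exp(-outer(b[idx], s2))
      w <- w * damp
    }
    contrib <- crossprod(w, occ[idx])             # nq x 1 complex
    acc <- acc + f_by_elem[el, ] * as.vector(contrib)
  }
  acc
}

# Evaluate the resultant amplitude for one snapshot at arbitrary q vectors,
# in pixel blocks bounded by a configurable element budget.
.amplitude_at_q <- function(snapshot, q, use_b = FALSE,
                            block_elements = getOption("xrdsim.block_elements", 4e6)) {
  xyz <- coords(snapshot)
  n <- nrow(xyz)
  nq <- nrow(q)
  block <- max(1L, min(nq, floor(block_elements / max(1L, n))))
  out <- complex(real = numeric(nq), imaginary = numeric(nq))
  s <- sqrt(rowSums(q^2)) / 2
  f_by_elem_full <- form_factor_matrix(snapshot$element, s)
  i0 <- 1L
  while (i0 <= nq) {
    i1 <- min(nq, i0 + block - 1L)
    out[i0:i1] <- .amplitude_block(xyz, snapshot$element, snapshot$occ,
                                   snapshot$b, q[i0:i1, , drop = FALSE],
                                   f_by_elem_full[, i0:i1, drop = FALSE], use_b)
    i0 <- i1 + 1L
  }
  out
}

#' Resultant diffraction amplitude at detector pixels
#'
#' Direct Huygens-Fresnel summation of secondary wavelets:
#' \deqn{A(p) = \sum_j o_j f_j(s(p)) \exp[i 2\pi\, r_j \cdot (k - k'(p))],}
#' over every atom in the snapshot — protein, water, ions and hydrogens
#' alike. Occupancy multiplies the atomic amplitude. Per-atom B factors
#' are ignored by default (the ensemble carries the small-scale motion);
#' set `use_b = TRUE` to honor them for static-structure use.
#'
#' @param snapshot an `atom_set`.
#' @param px pixel indices: length-2 vector or n x 2 matrix (fast, slow),
#'   0-based.
#' @param geom a [detector_geometry()].
#' @param use_b honor per-atom B factors (default FALSE).
#' @return complex amplitude(s) in electrons, one per pixel.
#' @export
amplitude_at_pixel <- function(snapshot, px, geom, use_b = FALSE) {
  q <- pixel_q(px, geom)
  .amplitude_at_q(snapshot, q, use_b = use_b)
}

#' Detector-free intensity probe of the wavelet sum
#'
#' Evaluates, at arbitrary reciprocal vectors q, the ensemble intensity
#' \deqn{I(q) = \sum_{\mathrm{snapshots}} \big|\sum_j o_j f_j(|q|/2)
#' \exp(i 2\pi r_j \cdot q)\big|^2}
#' — the same sum the photograph engine accumulates, without detector
#' geometry. Useful for symmetry (Friedel) and Debye-Waller checks.
#'
#' @param x an `atom_set` or `ensemble`.
#' @param q 3-vector or n x 3 matrix, inverse angstrom.
#' @param use_b honor per-atom B factors.
#' @return non-negative intensity, one value per q.
#' @export
intensity_at_q <- function(x, q, use_b = FALSE) {
  ens <- as_ensemble(x)
  q <- matrix(q, ncol = 3)
  out <- numeric(nrow(q))
  for (m in seq_len(n_frames(ens))) {
    a <- .amplitude_at_q(ensemble_frame(ens, m), q, use_b = use_b)
    out <- out + Re(a)^2 + Im(a)^2
  }
  out
}

# resolve the pixel set of a frame simulation: full raster, an explicit
# n x 2 subset, or the TRUE entries of a mask matrix
.resolve_pixels <- function(geom, pixels, mask) {
  if (!is.null(pixels)) {
    px <- matrix(pixels, ncol = 2)
  } else if (!is.null(mask)) {
    stopifnot(all(dim(mask) == geom$raster))
    idx <- which(mask) - 1L
    px <- cbind(idx %% geom$raster[1], idx %/% geom$raster[1])
  } else {
    px <- raster_pixels(geom)
  }
  px
}

.photo_from_values <- function(values, px, geom, frame, series, n_snap, engine) {
  img <- matrix(0, geom$raster[1], geom$raster[2])
  msk <- matrix(FALSE, geom$raster[1], geom$raster[2])
  lin <- px[, 1] + geom$raster[1] * px[, 2] + 1L
  img[lin] <- values
  msk[lin] <- TRUE
  photograph(img, frame = frame,
             angle_start = series$start + frame * series$frame_width,
             angle_width = series$frame_width,
             n_snapshots = n_snap, mask = msk, engine = engine)
}

#' Simulate one oscillation frame by direct summation
#'
#' Accumulates `|A_total|^2` over every ensemble snapshot and every
#' angular sub-step of the frame: snapshots contribute by intensity, as do
#' sub-steps (exposure adds intensities, never complex amplitudes between
#' snapshots). The crystal is first oriented by `orientation`, then
#' rotated about the lab x axis to each sub-step mid-point angle.
#'
#' @param ens an `ensemble` (or single `atom_set`).
#' @param geom a [detector_geometry()].
#' @param series a [rotation_series()].
#' @param orientation an [orientation_matrix()].
#' @param frame_index 0-based frame index within [frame_plan()].
#' @param pixels optional n x 2 matrix restricting simulation to given
#'   pixels (others masked).
#' @param mask optional logical matrix; `TRUE` pixels are simulated.
#' @param use_b honor per-atom B factors (default FALSE).
#' @return a [photograph()].
#' @export
simulate_frame <- function(ens, geom, series, orientation = orientation_matrix(),
                           frame_index = 0L, pixels = NULL, mask = NULL,
                           use_b = FALSE) {
  ens <- as_ensemble(ens)
  if (n_frames(ens) < 1) stop("simulate_frame: empty ensemble")
  plan <- frame_plan(series)
  if (frame_index < 0 || frame_index >= length(plan))
    stop("simulate_frame: frame index outside the frame plan")
  angles <- plan[[frame_index + 1]]$angles
  px <- .resolve_pixels(geom, pixels, mask)
  qlab <- pixel_q(px, geom)
  acc <- numeric(nrow(px))
  for (m in seq_len(n_frames(ens))) {
    snap <- ensemble_frame(ens, m)
    for (ang in angles) {
      rot <- rotation_about_axis(c(1, 0, 0), ang) %*% unclass(orientation)
      qcr <- qlab %*% rot      # phase r . (R^T q) == (R r) . q
      a <- .amplitude_at_q(snap, qcr, use_b = use_b)
      acc <- acc + Re(a)^2 + Im(a)^2
    }
  }
  .photo_from_values(acc, px, geom, frame_index, series, n_frames(ens), "direct")
}

#' Simulate a full rotation series
#'
#' Applies [simulate_frame()] over the frame plan; result count equals
#' total range / frame width (the experimental protocol: 180 one-degree
#' photographs covering 180 degrees). Emits one progress line per frame
#' via `message()`.
#'
#' @inheritParams simulate_frame
#' @param frames optional integer vector of 0-based frame indices
#'   (default: all frames).
#' @param quiet suppress progress messages.
#' @return list of [photograph()] objects.
#' @export
simulate_series <- function(ens, geom, series,
                            orientation = orientation_matrix(),
                            frames = NULL, pixels = NULL, mask = NULL,
                            use_b = FALSE, quiet = FALSE) {
  if (is.null(frames)) frames <- seq_len(series$n_frames) - 1L
  lapply(frames, function(fi) {
    if (!quiet)
      message(sprintf("xrdsim: frame %d/%d", fi + 1L, series$n_frames))
    simulate_frame(ens, geom, series, orientation, fi,
                   pixels = pixels, mask = mask, use_b = use_b)
  })
}

#' Per-frame provenance record
#'
#' @param photo a [photograph()].
#' @return JSON string describing the frame (angles, snapshot count,
#'   engine).
#' @export
photograph_provenance <- function(photo) {
  jsonlite::toJSON(list(frame = photo$frame,
                        angle_start = photo$angle_start,
                        angle_width = photo$angle_width,
                        n_snapshots = photo$n_snapshots,
                        engine = photo$engine),
                   auto_unbox = TRUE)
}
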