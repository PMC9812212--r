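# shared small fixtures for the suite

toy_geom <- function(n = 101L, pitch = 0.3, dist = 45, lambda = 1.54) {
  detector_geometry(lambda, dist, pitch, c(n, n), c((n - 1) / 2, (n - 1) / 2))
}

# independent per-atom complex-sum oracle for the wavelet superposition:
# plain double loop, scalar arithmetic, no shared code with the engine
oracle_amplitude <- function(snapshot, px, geom) {
  k <- c(0, 0, 1 / geom$wavelength)
  out <- complex(length(nrow(px)))
  d <- as.data.frame(snapshot)
  for (p in seq_len(nrow(px))) {
    pos_mm <- c((px[p, 1] - geom$beam_center[1]) * geom$pixel_mm,
                (px[p, 2] - geom$beam_center[2]) * geom$pixel_mm,
                geom$distance)
    kp <- pos_mm / sqrt(sum(pos_mm^2)) / geom$wavelength
    q <- k - kp
    s <- sqrt(sum(q^2)) / 2
    a <- 0 + 0i
    for (j in seq_len(nrow(d))) {
      f <- form_factor(d$element[j], s)
      delta <- 2 * pi * sum(c(d$x[j], d$y[j], d$z[j]) * q)
      a <- a + d$occ[j] * f * exp(1i * delta)
    }
    out[p] <- a
  }
  out
}

# random atom set with elements drawn from the shipped table
random_atom_set <- function(n, span = 20, seed = 1,
                            elements = c("C", "N", "O", "S", "H")) {
  set.seed(seed)
  atom_set(data.frame(element = sample(elements, n, replace = TRUE),
                      x = runif(n, -span, span), y = runif(n, -span, span),
                      z = runif(n, -span, span),
                      occ = runif(n, 0.5, 1), b = 0))
}

# one-ATOM-record PDB text
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = NULL, het = FALSE) {
  if (is.null(element)) element <- substr(name, 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, "", resname, chain,
          resno, "", x, y, z, occ, b, element)
}
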