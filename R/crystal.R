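#' Unit cell
#'
#' @param a,b,c cell edges in angstrom (> 0).
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return object of class `unit_cell`.
#' @examples
#' unit_cell(78.67, 78.67, 36.93)   # tetragonal lysozyme cell
#' @export
unit_cell <- function(a, b = a, c = a, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("unit_cell: lengths must be > 0")
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0 | ang >= 180)) stop("unit_cell: angles must lie in (0, 180)")
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Orthogonalization matrix of a unit cell
#'
#' Standard PDB convention: a along x, b in the x-y plane. Columns are the
#' cell vectors in angstrom, so `M %*% frac` converts fractional to
#' Cartesian coordinates.
#'
#' @param cell a [unit_cell()].
#' @return 3 x 3 matrix.
#' @export
orthogonalization_matrix <- function(cell) {
  d2r <- pi / 180
  ca <- cos(cell$alpha * d2r); cb <- cos(cell$beta * d2r)
  cg <- cos(cell$gamma * d2r); sg <- sin(cell$gamma * d2r)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("orthogonalization_matrix: degenerate cell")
  m <- matrix(c(cell$a, cell$b * cg, cell$c * cb,
                0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
                0,      0,           cell$c * sqrt(v2) / sg),
              nrow = 3, byrow = TRUE)
  m
}

#' @rdname orthogonalization_matrix
#' @export
fractionalization_matrix <- function(cell) solve(orthogonalization_matrix(cell))

# ---------------------------------------------------------------------------
# Space groups.  Operators are shipped as data (triplet strings in fractional
# coordinates); P1 and P43212 cover the tetragonal lysozyme case, and any
# group can be supplied through explicit operator strings.

.shipped_spacegroups <- list(
  "P1" = c("x,y,z"),
  "P43212" = c(
    "x,y,z",
    "-y+1/2,x+1/2,z+3/4",
    "-x,-y,z+1/2",
    "y+1/2,-x+1/2,z+1/4",
    "x+1/2,-y+1/2,-z+1/4",
    "-y,-x,-z+1/2",
    "-x+1/2,y+1/2,-z+3/4",
    "y,x,-z")
)

normalize_sg_name <- function(name) {
  toupper(gsub("[ _()]", "", name))
}

# Parse one symmetry triplet such as "-y+1/2,x+1/2,z+3/4" into a 3x3
# rotation matrix and translation 3-vector (fractional coordinates).
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", triplet), ",", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("parse_symop: expected 3 components in ", triplet)
  rot <- matrix(0, 3, 3); tra <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[terms != ""]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      low <- tolower(tm)
      if (low %in% c("x", "y", "z")) {
        rot[i, match(low, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", tm)) {
        f <- as.numeric(strsplit(tm, "/", fixed = TRUE)[[1]])
        tra[i] <- tra[i] + sign * f[1] / f[2]
      } else if (grepl("^[0-9.]+$", tm)) {
        tra[i] <- tra[i] + sign * as.numeric(tm)
      } else {
        stop("parse_symop: cannot parse term '", tm, "' in ", triplet)
      }
    }
  }
  list(rot = rot, trans = tra)
}

#' Space-group symmetry operators
#'
#' Shipped groups: P1 and P43212 (the tetragonal lysozyme group). Other
#' groups are accepted by passing their operator triplet strings
#' explicitly.
#'
#' @param name Hermann-Mauguin symbol (spaces/underscores ignored, e.g.
#'   `"P43212"` or `"P 43 21 2"`).
#' @param operators optional character vector of triplets
#'   (e.g. `c("x,y,z", "-x,-y,z+1/2")`) overriding the shipped table.
#' @return object of class `space_group` with fields `name`, `triplets`,
#'   `ops` (list of `rot`/`trans` pairs).
#' @export
space_group <- function(name, operators = NULL) {
  key <- normalize_sg_name(name)
  if (is.null(operators)) {
    if (!key %in% names(.shipped_spacegroups))
      stop("space_group: '", name, "' is not shipped; supply `operators` triplets")
    operators <- .shipped_spacegroups[[key]]
  }
  ops <- lapply(operators, parse_symop)
  structure(list(name = name, key = key, triplets = operators, ops = ops),
            class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("<space_group> %s (%d operators)\n", x$name, length(x$ops)))
  invisible(x)
}

#' @rdname space_group
#' @param sg a `space_group`.
#' @export
n_operators <- function(sg) length(sg$ops)

#' Supercell specification
#'
#' @param n_a,n_b,n_c positive integer replication counts along the cell
#'   axes.
#' @param cell a [unit_cell()].
#' @param sg a [space_group()].
#' @export
supercell_spec <- function(n_a, n_b, n_c, cell, sg) {
  n <- c(n_a, n_b, n_c)
  if (any(n < 1) || any(n != round(n)))
    stop("supercell_spec: replication counts must be positive integers")
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_c = as.integer(n_c), cell = cell, sg = sg),
            class = "supercell_spec")
}

#' Expand an asymmetric unit by space-group symmetry
#'
#' Each operator is applied in fractional coordinates
#' (fractionalize, apply, orthogonalize); no wrapping into the cell is
#' performed, so every copy is an exact rigid motion of the input.
#' Molecule indices are renumbered uniquely across copies.
#'
#' @param asu an `atom_set` holding the asymmetric unit.
#' @param sg a [space_group()].
#' @param cell a [unit_cell()].
#' @return an `atom_set` with `n_operators(sg) * n_atoms(asu)` atoms.
#' @export
expand_asymmetric_unit <- function(asu, sg, cell) {
  m <- orthogonalization_matrix(cell)
  minv <- solve(m)
  frac <- coords(asu) %*% t(minv)
  nmol <- max(asu$mol)
  pieces <- vector("list", length(sg$ops))
  for (i in seq_along(sg$ops)) {
    op <- sg$ops[[i]]
    f2 <- frac %*% t(op$rot)
    f2 <- sweep(f2, 2, op$trans, "+")
    copy <- asu
    coords(copy) <- f2 %*% t(m)
    copy$mol <- copy$mol + (i - 1L) * nmol
    pieces[[i]] <- as.data.frame(copy)
  }
  out <- do.call(rbind, pieces)
  out$id <- seq_len(nrow(out))
  atom_set(out)
}

#' Replicate one unit cell into an n_a x n_b x n_c supercell
#'
#' Translated copies are placed on the lattice grid defined by the cell
#' vectors; the supercell is an explicit finite block (no periodic
#' wrapping), matching the diffraction treatment.
#'
#' @param cell_contents an `atom_set` holding one full unit cell.
#' @param spec a [supercell_spec()].
#' @return an `atom_set` with `n_a * n_b * n_c` times as many atoms.
#' @export
build_supercell <- function(cell_contents, spec) {
  stopifnot(inherits(spec, "supercell_spec"))
  m <- orthogonalization_matrix(spec$cell)
  nmol <- max(cell_contents$mol)
  xyz <- coords(cell_contents)
  pieces <- vector("list", spec$n_a * spec$n_b * spec$n_c)
  idx <- 0L
  for (ic in seq_len(spec$n_c) - 1L)
    for (ib in seq_len(spec$n_b) - 1L)
      for (ia in seq_len(spec$n_a) - 1L) {
        idx <- idx + 1L
        shift <- as.vector(m %*% c(ia, ib, ic))
        copy <- cell_contents
        coords(copy) <- sweep(xyz, 2, shift, "+")
        copy$mol <- copy$mol + (idx - 1L) * nmol
        pieces[[idx]] <- as.data.frame(copy)
      }
  out <- do.call(rbind, pieces)
  out$id <- seq_len(nrow(out))
  atom_set(out)
}

# random rotation matrix from a uniform quaternion
.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-12) { q <- q / n; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rigid 3-site water centered on the oxygen: O-H 1.0 A, H-O-H 109.47 deg
.water_template <- function() {
  half <- (109.47 / 2) * pi / 180
  rbind(c(0, 0, 0),
        c(sin(half), cos(half), 0),
        c(-sin(half), cos(half), 0))
}

#' Add randomly placed rigid waters to a system
#'
#' Rigid 3-site waters (O-H 1.0 angstrom, H-O-H 109.47 degrees) are placed
#' with uniformly random position and orientation inside the box,
#' rejection-sampled so that every new oxygen lies at least `min_dist`
#' from all existing heavy atoms and previously placed water oxygens.
#' Deterministic for a fixed seed.
#'
#' @param host an `atom_set` (may have zero rows via an empty box — pass a
#'   0-row atom set).
#' @param box length-3 vector: box edges in angstrom (origin at 0).
#' @param n_waters number of waters to add.
#' @param min_dist minimum oxygen-to-heavy-atom distance in angstrom.
#' @param seed integer RNG seed.
#' @param max_attempts attempt budget per water before giving up.
#' @return an `atom_set` with `3 * n_waters` additional atoms.
#' @export
solvate_random <- function(host, box, n_waters, min_dist = 2.4, seed = 1,
                           max_attempts = 10000L) {
  stopifnot(length(box) == 3, all(box > 0), min_dist > 0, n_waters >= 0)
  if (n_waters == 0) return(host)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  heavy <- coords(host)[host$element != "H", , drop = FALSE]
  placed <- matrix(0, 0, 3)
  wt <- .water_template()
  rows <- vector("list", n_waters)
  mol0 <- if (nrow(host)) max(host$mol) else 0L
  res0 <- if (nrow(host)) max(host$resno) else 0L
  for (w in seq_len(n_waters)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      o <- stats::runif(3) * box
      ref <- rbind(heavy, placed)
      if (nrow(ref)) {
        d2 <- (ref[, 1] - o[1])^2 + (ref[, 2] - o[2])^2 + (ref[, 3] - o[3])^2
        if (min(d2) < min_dist^2) next
      }
      rot <- .random_rotation()
      sites <- sweep(wt %*% t(rot), 2, o, "+")
      rows[[w]] <- data.frame(
        element = c("O", "H", "H"),
        name = c("O", "H1", "H2"), resname = "HOH",
        resno = res0 + w, chain = "W", mol = mol0 + w,
        x = sites[, 1], y = sites[, 2], z = sites[, 3],
        occ = 1, b = 0, stringsAsFactors = FALSE)
      placed <- rbind(placed, o)
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(paste0("solvate_random: placement failed after %d attempts; ",
                          "%d of %d waters placed"), max_attempts, w - 1L, n_waters))
  }
  new <- do.call(rbind, rows)
  combined <- rbind(as.data.frame(host)[, setdiff(names(host), "id")],
                    new)
  combined$id <- seq_len(nrow(combined))
  atom_set(combined)
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Default formal-charge scheme
#'
#' Arg/Lys +1, Asp/Glu -1, neutral His, waters and common neutral residues
#' 0. Protonation variants (e.g. protonated Asp "ASH" / Glu "GLH") are
#' entries in the table and default to 0. Chain termini are not treated
#' separately (a zwitterionic terminus pair is net neutral).
#'
#' @return named numeric vector: residue label to formal charge.
#' @export
default_charge_scheme <- function() {
  ch <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1, HIS = 0,
          ASH = 0, GLH = 0, CYX = 0, HID = 0, HIE = 0, HIP = 1)
  neutral <- c("ALA", "ASN", "CYS", "GLN", "GLY", "ILE", "LEU", "MET",
               "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL", "HOH",
               "WAT", "UNK")
  c(ch, stats::setNames(rep(0, length(neutral)), neutral))
}

#' Neutralize a system with monatomic counterions
#'
#' Computes the net formal charge from a per-residue charge table and adds
#' enough monatomic ions of the given element, at random non-clashing
#' positions inside the host bounding box, to bring the formal charge
#' to zero.
#'
#' @param host an `atom_set`.
#' @param charge_scheme named numeric vector mapping residue labels to
#'   formal charges; see [default_charge_scheme()].
#' @param ion_element element symbol of the counterion (e.g. `"CL"` for
#'   chloride against a positive net charge, `"NA"` against a negative).
#' @param seed integer RNG seed.
#' @param min_dist minimum ion-to-heavy-atom distance, angstrom.
#' @return an `atom_set` with `ceiling(abs(net charge))` added ions.
#' @export
neutralize <- function(host, charge_scheme = default_charge_scheme(),
                       ion_element = "CL", seed = 1, min_dist = 2.4) {
  res <- unique(as.data.frame(host)[, c("chain", "resno", "resname", "mol")])
  missing <- setdiff(unique(res$resname),
                     c(names(charge_scheme), toupper(ion_element)))
  if (length(missing))
    stop("neutralize: residues missing from charge scheme: ",
         paste(missing, collapse = ", "))
  known <- res$resname %in% names(charge_scheme)
  net <- sum(charge_scheme[res$resname[known]])
  n_ions <- ceiling(abs(net))
  if (n_ions == 0) return(host)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  heavy <- coords(host)[host$element != "H", , drop = FALSE]
  lo <- apply(heavy, 2, min); hi <- apply(heavy, 2, max)
  placed <- matrix(0, 0, 3)
  pos <- matrix(0, n_ions, 3)
  for (i in seq_len(n_ions)) {
    for (att in seq_len(10000L)) {
      p <- lo + stats::runif(3) * (hi - lo)
      ref <- rbind(heavy, placed)
      d2 <- (ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2 + (ref[, 3] - p[3])^2
      if (min(d2) >= min_dist^2) { pos[i, ] <- p; placed <- rbind(placed, p); break }
      if (att == 10000L) stop("neutralize: could not place ion ", i)
    }
  }
  el <- toupper(ion_element)
  new <- data.frame(element = el, name = el, resname = el,
                    resno = max(host$resno) + seq_len(n_ions),
                    chain = "I", mol = max(host$mol) + seq_len(n_ions),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    occ = 1, b = 0, stringsAsFactors = FALSE)
  combined <- rbind(as.data.frame(host)[, setdiff(names(host), "id")], new)
  combined$id <- seq_len(nrow(combined))
  atom_set(combined)
}
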