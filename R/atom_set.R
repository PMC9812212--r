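#' Labeled atom sets
#'
#' An `atom_set` is the universal coordinate container of the package: a
#' data frame of atoms with element, Cartesian position (angstrom),
#' occupancy and per-atom B factor (angstrom^2), plus residue/atom labels
#' and a molecule index that partitions atoms into rigid-body groups (one
#' protein copy, one water or one ion per group). The same container holds
#' an asymmetric unit, a full unit cell, a supercell, or one ensemble
#' snapshot.
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z`; optional
#'   columns `id`, `name`, `resname`, `resno`, `chain`, `mol`, `occ`, `b`
#'   are filled with defaults when absent.
#' @return An object of class `atom_set` (a validated data frame).
#' @examples
#' a <- atom_set(data.frame(element = "C", x = 0, y = 0, z = 0))
#' n_atoms(a)
#' @export
atom_set <- function(atoms) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom_set: missing required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$id))      atoms$id      <- seq_len(n)
  if (is.null(atoms$name))    atoms$name    <- atoms$element
  if (is.null(atoms$resname)) atoms$resname <- rep("UNK", n)
  if (is.null(atoms$resno))   atoms$resno   <- rep(1L, n)
  if (is.null(atoms$chain))   atoms$chain   <- rep("A", n)
  if (is.null(atoms$mol))     atoms$mol     <- rep(1L, n)
  if (is.null(atoms$occ))     atoms$occ     <- rep(1, n)
  if (is.null(atoms$b))       atoms$b       <- rep(0, n)
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(pos)))
    stop("atom_set: non-finite coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("atom_set: occupancy outside [0, 1]")
  if (any(atoms$b < 0))
    stop("atom_set: negative B factor")
  atoms$element <- toupper(trimws(as.character(atoms$element)))
  atoms$mol <- as.integer(atoms$mol)
  class(atoms) <- c("atom_set", "data.frame")
  atoms
}

#' @rdname atom_set
#' @param x an `atom_set`.
#' @export
n_atoms <- function(x) nrow(x)

#' Coordinate matrix of an atom set
#'
#' @param x an `atom_set` (or ensemble frame).
#' @return numeric n x 3 matrix of Cartesian coordinates in angstrom.
#' @export
coords <- function(x) {
  m <- as.matrix(as.data.frame(x)[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of an atom set
#'
#' @param x an `atom_set`.
#' @param value n x 3 matrix.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(nrow(value) == nrow(x), ncol(value) == 3)
  x$x <- value[, 1]; x$y <- value[, 2]; x$z <- value[, 3]
  x
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("<atom_set> %d atoms, %d molecule(s), elements: %s\n",
              nrow(x), length(unique(x$mol)),
              paste(sort(unique(x$element)), collapse = " ")))
  invisible(x)
}

#' Coordinate ensembles
#'
#' An `ensemble` is an ordered list of snapshots sharing one atom roster —
#' the stand-in for molecular-dynamics frames. It stores the roster once
#' and the coordinates as an n_atoms x 3 x n_frames array.
#'
#' @param frames either a list of `atom_set`s with identical rosters, or a
#'   single `atom_set` (the roster) together with `coords_array`.
#' @param coords_array optional n x 3 x m array of coordinates.
#' @return An object of class `ensemble` with fields `atoms` (roster) and
#'   `coords` (array).
#' @export
ensemble <- function(frames, coords_array = NULL) {
  if (inherits(frames, "atom_set")) {
    roster <- frames
    if (is.null(coords_array)) {
      coords_array <- array(coords(roster), dim = c(nrow(roster), 3, 1))
    }
  } else {
    stopifnot(is.list(frames), length(frames) >= 1)
    roster <- frames[[1]]
    ns <- vapply(frames, nrow, 1L)
    if (any(ns != ns[1]))
      stop("ensemble: frames differ in atom count")
    coords_array <- array(0, dim = c(ns[1], 3, length(frames)))
    for (i in seq_along(frames)) coords_array[, , i] <- coords(frames[[i]])
  }
  stopifnot(length(dim(coords_array)) == 3, dim(coords_array)[1] == nrow(roster),
            dim(coords_array)[2] == 3)
  structure(list(atoms = roster, coords = coords_array), class = "ensemble")
}

#' @rdname ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  dim(x$coords)[3]
}

#' Extract one snapshot of an ensemble as an atom set
#'
#' @param x an `ensemble`.
#' @param i frame index (1-based).
#' @export
ensemble_frame <- function(x, i) {
  stopifnot(inherits(x, "ensemble"), i >= 1, i <= n_frames(x))
  fr <- x$atoms
  cc <- x$coords[, , i, drop = FALSE]
  dim(cc) <- dim(x$coords)[1:2]
  coords(fr) <- cc
  fr
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d atoms\n", n_frames(x), nrow(x$atoms)))
  invisible(x)
}

# Known element symbols used for atom-name fallback inference.
.known_elements <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "MN", "FE", "CO", "NI", "CU",
  "ZN", "BR", "I", "SE"
)

# Infer an element symbol from a PDB atom name; "" when inference fails.
# Two-letter symbols are only trusted for HETATM records — polymer atom
# names like "CA" (C-alpha) or "CD" must resolve to their first letter.
infer_element <- function(name, het = FALSE) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (nchar(nm) == 0) return("")
  if (substr(nm, 1, 1) %in% c("H", "D")) return("H")
  if (het && nchar(nm) >= 2 && substr(nm, 1, 2) %in% .known_elements)
    return(substr(nm, 1, 2))
  first <- substr(nm, 1, 1)
  if (first %in% .known_elements) return(first)
  if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% .known_elements)
    return(substr(nm, 1, 2))
  ""
}

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "SPC", "DOD")
.ion_resnames   <- c("CL", "NA", "K", "MG", "CA", "ZN", "BR", "IOD", "CS", "LI")

#' Read atomic coordinates from a PDB file
#'
#' Wraps `bio3d::read.pdb`. Every ATOM/HETATM record becomes one atom;
#' the element is taken from the element column, falling back to inference
#' from the atom name. Molecule indices are assigned per chain for polymer
#' atoms and per residue for waters and monatomic ions. Multi-model files
#' return an [ensemble()] of snapshots sharing one roster.
#'
#' @param file path to a PDB file, or (with `text = TRUE`) a character
#'   scalar holding PDB-format text.
#' @param text logical; interpret `file` as literal PDB text.
#' @return An `atom_set` for single-model input, an `ensemble` for
#'   multi-model input. The unit cell and space group from a CRYST1
#'   record, when present, are attached as attributes `cell` and
#'   `spacegroup_name`.
#' @export
read_structure <- function(file, text = FALSE) {
  if (text) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(strsplit(file, "\n", fixed = TRUE)[[1]], tf)
    file <- tf
  }
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("read_structure: no ATOM/HETATM records")
  het <- at$type == "HETATM"
  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  need <- which(elem == "" | !(elem %in% .known_elements))
  if (length(need)) {
    inferred <- mapply(infer_element, at$elety[need], het[need],
                       USE.NAMES = FALSE)
    bad <- need[inferred == ""]
    if (length(bad))
      stop("read_structure: cannot determine element for atom(s): ",
           paste(sprintf("#%d %s/%s", at$eleno[bad], at$resid[bad],
                         at$elety[bad]), collapse = ", "))
    elem[need] <- inferred
  }
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  resname <- toupper(trimws(at$resid))
  solvent_like <- resname %in% c(.water_resnames, .ion_resnames)
  mol_key <- ifelse(solvent_like,
                    paste0("S|", chain, "|", resname, "|", at$resno),
                    paste0("C|", chain))
  mol <- as.integer(factor(mol_key, levels = unique(mol_key)))
  roster <- atom_set(data.frame(
    id = at$eleno, element = elem, name = trimws(at$elety),
    resname = resname, resno = at$resno, chain = chain, mol = mol,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b) | at$b < 0, 0, at$b),
    stringsAsFactors = FALSE))
  # CRYST1 record parsed directly (fixed-column fields of the PDB format)
  cr <- grep("^CRYST1", readLines(file, warn = FALSE), value = TRUE)
  if (length(cr)) {
    cr <- cr[1]
    num <- function(from, to) suppressWarnings(as.numeric(substr(cr, from, to)))
    abc <- c(num(7, 15), num(16, 24), num(25, 33))
    ang <- c(num(34, 40), num(41, 47), num(48, 54))
    if (all(is.finite(abc)) && all(abc > 0) && all(is.finite(ang))) {
      attr(roster, "cell") <- unit_cell(abc[1], abc[2], abc[3],
                                        ang[1], ang[2], ang[3])
      attr(roster, "spacegroup_name") <- trimws(substr(cr, 56, 66))
    }
  }
  nmod <- nrow(pdb$xyz)
  if (is.null(nmod) || nmod <= 1) return(roster)
  arr <- array(0, dim = c(nrow(roster), 3, nmod))
  for (m in seq_len(nmod))
    arr[, , m] <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  ensemble(roster, arr)
}

#' Write an atom set (or ensemble) as a PDB file
#'
#' ATOM records are produced through `bio3d::write.pdb`; a CRYST1 record
#' carrying the supplied cell (for a constructed supercell, the supercell
#' box) is prepended. Ensembles are written as MODEL/ENDMDL blocks.
#'
#' @param x an `atom_set` or `ensemble`.
#' @param file output path.
#' @param cell optional [unit_cell()] written into CRYST1.
#' @param spacegroup_name optional Hermann-Mauguin symbol for CRYST1.
#' @export
write_structure <- function(x, file, cell = NULL, spacegroup_name = "P 1") {
  one_block <- function(as) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    bio3d::write.pdb(file = tf,
                     xyz = as.vector(t(coords(as))),
                     type = rep("ATOM", nrow(as)),
                     resno = as$resno, resid = as$resname,
                     eleno = seq_len(nrow(as)) %% 100000L,
                     elety = as$name, chain = substr(as$chain, 1, 1),
                     o = as$occ, b = as$b, elesy = as$element)
    ln <- readLines(tf)
    ln[grepl("^(ATOM|HETATM|TER)", ln)]
  }
  out <- character(0)
  if (!is.null(cell)) {
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
                   spacegroup_name, 1L)
  }
  if (inherits(x, "ensemble")) {
    for (m in seq_len(n_frames(x))) {
      out <- c(out, sprintf("MODEL %8d", m), one_block(ensemble_frame(x, m)),
               "ENDMDL")
    }
  } else {
    out <- c(out, one_block(x))
  }
  writeLines(c(out, "END"), file)
  invisible(file)
}
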