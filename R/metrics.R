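# Ensemble-dynamics analysis: periodic-jump correction, best-fit and
# lattice r.m.s.d./r.m.s.f., B factors from fluctuations, B-profile
# correlations, and ordered-water matching by hydrogen-bond criteria.

#' Correct periodic jumps of molecules in a supercell trajectory
#'
#' Whenever a molecule's center displaces by more than half a box vector
#' between consecutive frames, the integer box-vector shift minimizing
#' the displacement is applied to that molecule from that frame onward,
#' making trajectories continuous (mass transfer across the periodic
#' boundary is an artifact of the simulation protocol, not physics).
#'
#' @param ens an `ensemble`.
#' @param box length-3 vector of box edges, angstrom (> 0).
#' @return the unwrapped `ensemble`.
#' @export
unwrap_periodic <- function(ens, box) {
  stopifnot(inherits(ens, "ensemble"))
  if (any(box <= 0)) stop("unwrap_periodic: box edges must be > 0")
  mols <- split(seq_len(nrow(ens$atoms)), ens$atoms$mol)
  out <- ens
  nf <- n_frames(ens)
  for (idx in mols) {
    cc1 <- out$coords[idx, , 1, drop = FALSE]
    dim(cc1) <- c(length(idx), 3)
    prev_center <- colMeans(cc1)
    shift <- c(0, 0, 0)
    for (f in seq_len(nf)[-1]) {
      cc <- out$coords[idx, , f, drop = FALSE]
      dim(cc) <- c(length(idx), 3)
      center <- colMeans(cc) + shift
      jump <- round((center - prev_center) / box)
      shift <- shift - jump * box
      if (any(jump != 0) || any(shift != 0))
        cc <- sweep(cc, 2, shift, "+")
      out$coords[idx, , f] <- cc
      prev_center <- colMeans(cc)
    }
  }
  out
}

# Kabsch optimal rotation aligning x (n x 3) onto y (n x 3), both already
# centered; returns R such that x %*% R is closest to y (row-vector
# convention, proper rotation enforced via the determinant sign).
.kabsch <- function(x, y) {
  h <- crossprod(x, y)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# resolve a selection on a roster to row indices within one molecule
.selection_idx <- function(atoms, selection) {
  if (is.null(selection) || identical(selection, "all"))
    return(seq_len(nrow(atoms)))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.logical(selection)) return(which(selection))
  bb <- c("N", "CA", "C", "O", "OXT")
  switch(selection,
         calpha = which(atoms$name == "CA"),
         heavy = which(atoms$element != "H"),
         backbone = which(atoms$name %in% bb & atoms$element != "H"),
         sidechain_heavy = which(!(atoms$name %in% bb) & atoms$element != "H"),
         stop("unknown selection: ", selection))
}

#' Best-fit r.m.s.d. between a snapshot and a reference
#'
#' Each molecule of the snapshot is optimally superposed (least-squares
#' rotation + translation, Kabsch) onto the corresponding molecule of the
#' reference — molecules correspond by roster order within their molecule
#' index — and the r.m.s.d. over selected atoms is computed per molecule.
#' When the reference holds a single molecule, every snapshot molecule is
#' fitted onto it.
#'
#' @param snapshot,reference `atom_set`s with equal selected-atom counts
#'   per molecule.
#' @param selection `"all"`, `"calpha"`, `"heavy"`, `"backbone"`,
#'   `"sidechain_heavy"`, or an index/logical vector applied per
#'   molecule.
#' @return numeric vector of per-molecule r.m.s.d. values (angstrom);
#'   the mean is attached as attribute `mean`.
#' @export
best_fit_rmsd <- function(snapshot, reference, selection = "all") {
  smols <- split(seq_len(nrow(snapshot)), snapshot$mol)
  rmols <- split(seq_len(nrow(reference)), reference$mol)
  single_ref <- length(rmols) == 1 && length(smols) >= 1
  if (!single_ref && length(smols) != length(rmols))
    stop("best_fit_rmsd: molecule count mismatch")
  sx <- coords(snapshot); rx <- coords(reference)
  out <- numeric(length(smols))
  for (i in seq_along(smols)) {
    si <- smols[[i]]
    ri <- if (single_ref) rmols[[1]] else rmols[[i]]
    if (length(si) != length(ri))
      stop("best_fit_rmsd: atom count mismatch in molecule ", i)
    sel <- .selection_idx(snapshot[si, , drop = FALSE], selection)
    a <- sx[si[sel], , drop = FALSE]
    b <- rx[ri[sel], , drop = FALSE]
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    rot <- .kabsch(ac, bc)
    dif <- ac %*% rot - bc
    out[i] <- sqrt(mean(rowSums(dif^2)))
  }
  attr(out, "mean") <- mean(out)
  out
}

#' Lattice r.m.s.d. between a snapshot and a reference supercell
#'
#' The snapshot is translated so the centers of mass of the two complete
#' systems coincide — no rotation, so displacement and reorientation of
#' molecules within the lattice contribute fully — and the r.m.s.d. over
#' selected atoms is returned.
#'
#' @inheritParams best_fit_rmsd
#' @return scalar r.m.s.d., angstrom.
#' @export
lattice_rmsd <- function(snapshot, reference, selection = "all") {
  if (nrow(snapshot) != nrow(reference))
    stop("lattice_rmsd: atom roster mismatch")
  sel <- .selection_idx(snapshot, selection)
  sx <- coords(snapshot); rx <- coords(reference)
  sx <- sweep(sx, 2, colMeans(sx) - colMeans(rx))   # align centers of mass
  dif <- sx[sel, , drop = FALSE] - rx[sel, , drop = FALSE]
  sqrt(mean(rowSums(dif^2)))
}

#' Atomic root-mean-square fluctuation of an ensemble
#'
#' Per-frame alignment follows the chosen mode: `"best_fit"` superposes
#' every molecule copy onto the reference molecule (Kabsch), `"lattice"`
#' translates each whole frame so its center of mass matches the
#' reference supercell (apply [unwrap_periodic()] first for wrapped
#' trajectories). Fluctuations are taken about each copy's own mean
#' position and pooled over copies and frames, yielding one r.m.s.f. per
#' atom of the (single-molecule) roster.
#'
#' @param ens an `ensemble` (>= 2 frames).
#' @param reference reference `atom_set` (a single molecule for
#'   `"best_fit"`; the full supercell for `"lattice"`).
#' @param mode `"best_fit"` or `"lattice"`.
#' @param selection selection applied within each molecule (see
#'   [best_fit_rmsd()]).
#' @return numeric vector of per-atom r.m.s.f. values, angstrom.
#' @export
rmsf <- function(ens, reference, mode = c("best_fit", "lattice"),
                 selection = "all") {
  mode <- match.arg(mode)
  if (n_frames(ens) < 2) stop("rmsf: need at least 2 frames")
  nf <- n_frames(ens)
  mols <- split(seq_len(nrow(ens$atoms)), ens$atoms$mol)
  npm <- lengths(mols)
  if (length(unique(npm)) != 1)
    stop("rmsf: molecule copies differ in atom count")
  sel <- .selection_idx(ens$atoms[mols[[1]], , drop = FALSE], selection)
  nsel <- length(sel)
  ncopy <- length(mols)
  rx <- coords(reference)
  if (mode == "best_fit") {
    rmols <- split(seq_len(nrow(reference)), reference$mol)
    rref <- rx[rmols[[1]][sel], , drop = FALSE]
    rref <- sweep(rref, 2, colMeans(rref))
  }
  # aligned positions: nsel x 3 x (copy, frame)
  pos <- array(0, dim = c(nsel, 3, ncopy, nf))
  for (f in seq_len(nf)) {
    cc <- ens$coords[, , f]
    if (mode == "lattice")
      cc <- sweep(cc, 2, colMeans(cc) - colMeans(rx))
    for (ci in seq_len(ncopy)) {
      a <- cc[mols[[ci]][sel], , drop = FALSE]
      if (mode == "best_fit") {
        ac <- sweep(a, 2, colMeans(a))
        rot <- .kabsch(ac, rref)
        a <- ac %*% rot
      }
      pos[, , ci, f] <- a
    }
  }
  msd <- numeric(nsel)
  for (ci in seq_len(ncopy)) {
    arr <- pos[, , ci, , drop = FALSE]
    dim(arr) <- c(nsel, 3, nf)
    pm <- apply(arr, c(1, 2), mean)
    dev <- sweep(arr, c(1, 2), pm)
    msd <- msd + apply(dev^2, 1, sum) / nf
  }
  sqrt(msd / ncopy)
}

#' Convert r.m.s.f. to an isotropic B factor
#'
#' `B = (8 pi^2 / 3) * rmsf^2` — valid for Gaussian (harmonic,
#' small-amplitude) fluctuations.
#'
#' @param r r.m.s.f. in angstrom (vectorized, >= 0).
#' @return B factor(s) in angstrom^2.
#' @examples
#' b_from_rmsf(1)        # 8 pi^2 / 3 = 26.3189...
#' rmsf_from_b(b_from_rmsf(0.5))
#' @export
b_from_rmsf <- function(r) {
  if (any(r < 0)) stop("b_from_rmsf: negative r.m.s.f.")
  (8 * pi^2 / 3) * r^2
}

#' @rdname b_from_rmsf
#' @param b B factor(s), angstrom^2.
#' @export
rmsf_from_b <- function(b) {
  if (any(b < 0)) stop("rmsf_from_b: negative B")
  sqrt(3 * b / (8 * pi^2))
}

#' Per-residue B-factor profile of an atom set
#'
#' @param x an `atom_set` carrying per-atom B factors.
#' @param selection `"calpha"` (B of the C-alpha atom) or
#'   `"sidechain_heavy"` (mean over side-chain heavy atoms).
#' @return data frame with `resno` and `b`.
#' @export
b_profile <- function(x, selection = c("calpha", "sidechain_heavy")) {
  selection <- match.arg(selection)
  idx <- .selection_idx(x, selection)
  d <- as.data.frame(x)[idx, ]
  agg <- stats::aggregate(b ~ resno, data = d, FUN = mean)
  agg[order(agg$resno), ]
}

#' Pearson correlation between two aligned B-factor profiles
#'
#' @param p1,p2 numeric vectors (or `b_profile` data frames) of equal
#'   length, >= 3 entries, non-zero variance.
#' @return Pearson r in [-1, 1].
#' @export
b_profile_correlation <- function(p1, p2) {
  v1 <- if (is.data.frame(p1)) p1$b else p1
  v2 <- if (is.data.frame(p2)) p2$b else p2
  if (length(v1) != length(v2)) stop("b_profile_correlation: length mismatch")
  if (length(v1) < 3) stop("b_profile_correlation: need >= 3 entries")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("b_profile_correlation: zero variance")
  stats::cor(v1, v2)
}

#' Hydrogen-bond criteria
#'
#' @param max_da_dist maximum donor-acceptor distance, angstrom
#'   (default 3.5).
#' @param min_dha_angle minimum D-H...A angle at the hydrogen, degrees
#'   (default 150).
#' @export
hbond_criteria <- function(max_da_dist = 3.5, min_dha_angle = 150) {
  stopifnot(max_da_dist > 0, min_dha_angle > 0, min_dha_angle < 180)
  structure(list(max_da_dist = max_da_dist, min_dha_angle = min_dha_angle),
            class = "hbond_criteria")
}

#' Hydrogen-bond test for a donor-hydrogen-acceptor triple
#'
#' True iff `|D - A| < max_da_dist` and the D-H...A angle at the hydrogen
#' exceeds `min_dha_angle`.
#'
#' @param donor,hydrogen,acceptor 3-vectors, angstrom.
#' @param crit an [hbond_criteria()].
#' @export
hbond <- function(donor, hydrogen, acceptor, crit = hbond_criteria()) {
  v1 <- donor - hydrogen; v2 <- acceptor - hydrogen
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9) stop("hbond: coincident donor and hydrogen")
  if (n2 < 1e-9) stop("hbond: coincident acceptor and hydrogen")
  da <- sqrt(sum((donor - acceptor)^2))
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  da < crit$max_da_dist && ang > crit$min_dha_angle
}

# enumerate water-protein hydrogen bonds of one structure; returns a data
# frame (water molecule id, partner key, capacity).  Water capacity
# "donor": water O donates via one of its H atoms (H placed along
# O -> acceptor at 1.0 A when the water carries no hydrogens); capacity
# "acceptor": a protein N/O donates (its H likewise placed along
# D -> O_water at 1.0 A when absent).
.water_protein_hbonds <- function(x, crit) {
  d <- as.data.frame(x)
  is_w <- d$resname %in% .water_resnames
  if (!any(is_w)) return(data.frame(water = integer(0), partner = character(0),
                                    capacity = character(0)))
  prot <- d[!is_w & !(d$resname %in% .ion_resnames), ]
  if (!nrow(prot)) stop("match_ordered_waters: no protein atoms")
  polar <- prot[prot$element %in% c("N", "O"), ]
  ph <- prot[prot$element == "H", ]
  pxyz <- as.matrix(polar[, c("x", "y", "z")])
  key <- paste(polar$chain, polar$resno, polar$resname, polar$name, sep = ":")
  res <- list(); ri <- 0L
  for (w in unique(d$mol[is_w])) {
    wa <- d[d$mol == w & is_w, ]
    o <- wa[wa$element == "O", ]
    if (!nrow(o)) next
    op <- as.numeric(o[1, c("x", "y", "z")])
    wh <- wa[wa$element == "H", ]
    d2 <- (pxyz[, 1] - op[1])^2 + (pxyz[, 2] - op[2])^2 + (pxyz[, 3] - op[3])^2
    near <- which(d2 < crit$max_da_dist^2 & d2 > 1e-6)
    for (j in near) {
      ap <- pxyz[j, ]
      # water as donor
      ok_don <- FALSE
      if (nrow(wh)) {
        for (hj in seq_len(nrow(wh))) {
          hp <- as.numeric(wh[hj, c("x", "y", "z")])
          if (hbond(op, hp, ap, crit)) { ok_don <- TRUE; break }
        }
      } else {
        hp <- op + (ap - op) / sqrt(sum((ap - op)^2))   # geometric stand-in
        ok_don <- hbond(op, hp, ap, crit)
      }
      if (ok_don) {
        ri <- ri + 1L
        res[[ri]] <- data.frame(water = w, partner = key[j],
                                capacity = "donor")
      }
      # water as acceptor: protein polar atom donates
      don_h <- if (nrow(ph)) {
        hh <- as.matrix(ph[, c("x", "y", "z")])
        hd2 <- (hh[, 1] - ap[1])^2 + (hh[, 2] - ap[2])^2 + (hh[, 3] - ap[3])^2
        which(hd2 < 1.3^2)
      } else integer(0)
      ok_acc <- FALSE
      if (length(don_h)) {
        for (hj in don_h) {
          hp <- as.numeric(ph[hj, c("x", "y", "z")])
          if (hbond(ap, hp, op, crit)) { ok_acc <- TRUE; break }
        }
      } else {
        hp <- ap + (op - ap) / sqrt(sum((op - ap)^2))
        ok_acc <- hbond(ap, hp, op, crit)
      }
      if (ok_acc) {
        ri <- ri + 1L
        res[[ri]] <- data.frame(water = w, partner = key[j],
                                capacity = "acceptor")
      }
    }
  }
  if (!ri) return(data.frame(water = integer(0), partner = character(0),
                             capacity = character(0)))
  unique(do.call(rbind, res))
}

#' Match ordered waters between two structures by hydrogen bonding
#'
#' Two structures are considered to contain an identical ordered water
#' when a water in each forms a hydrogen bond to the same protein atom in
#' the same capacity (donor or acceptor). Water-protein hydrogen bonds
#' are enumerated in both structures; waters match when they share at
#' least one (partner atom, capacity) pair, and a greedy 1:1 assignment
#' by partner overlap (ties broken by O-O distance) yields the matched
#' count. When waters or protein donors carry no hydrogens, H positions
#' are placed along the donor-to-acceptor direction at 1.0 angstrom — a
#' documented geometric stand-in, flagged in the result.
#'
#' @param a,b `atom_set`s with protein atoms under consistent
#'   residue/atom naming and waters (residue label HOH/WAT/...).
#' @param crit an [hbond_criteria()].
#' @return list with `matched` (count), `mapping` (data frame: water id
#'   in `a`, water id in `b`, shared partner count), `hydrogens_placed`
#'   (logical).
#' @export
match_ordered_waters <- function(a, b, crit = hbond_criteria()) {
  ha <- .water_protein_hbonds(a, crit)
  hb_ <- .water_protein_hbonds(b, crit)
  placed <- !any(a$element[a$resname %in% .water_resnames] == "H") ||
    !any(b$element[b$resname %in% .water_resnames] == "H")
  if (!nrow(ha) || !nrow(hb_))
    return(list(matched = 0L,
                mapping = data.frame(water_a = integer(0), water_b = integer(0),
                                     shared = integer(0)),
                hydrogens_placed = placed))
  ha$pc <- paste(ha$partner, ha$capacity)
  hb_$pc <- paste(hb_$partner, hb_$capacity)
  wa <- unique(ha$water); wb <- unique(hb_$water)
  overlap <- matrix(0L, length(wa), length(wb))
  for (i in seq_along(wa))
    for (j in seq_along(wb))
      overlap[i, j] <- length(intersect(ha$pc[ha$water == wa[i]],
                                        hb_$pc[hb_$water == wb[j]]))
  oo_dist <- function(wi, wj) {
    oa <- as.data.frame(a); ob <- as.data.frame(b)
    pa <- oa[oa$mol == wi & oa$element == "O", c("x", "y", "z")][1, ]
    pb <- ob[ob$mol == wj & ob$element == "O", c("x", "y", "z")][1, ]
    sqrt(sum((as.numeric(pa) - as.numeric(pb))^2))
  }
  mapping <- list(); mi <- 0L
  repeat {
    best <- which(overlap == max(overlap) & overlap > 0, arr.ind = TRUE)
    if (!nrow(best)) break
    if (nrow(best) > 1) {
      dd <- apply(best, 1, function(r) oo_dist(wa[r[1]], wb[r[2]]))
      best <- best[which.min(dd), , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    mi <- mi + 1L
    mapping[[mi]] <- data.frame(water_a = wa[i], water_b = wb[j],
                                shared = overlap[i, j])
    overlap[i, ] <- 0L; overlap[, j] <- 0L
  }
  mapping <- if (mi) do.call(rbind, mapping)
             else data.frame(water_a = integer(0), water_b = integer(0),
                             shared = integer(0))
  list(matched = nrow(mapping), mapping = mapping,
       hydrogens_placed = placed)
}
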