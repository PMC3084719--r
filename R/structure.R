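# Structure data model: flexible peptide chain (torsion-space), rigid
# receptor, complex pose, and PDB I/O.
#
# Atom layout: every residue is represented by five sites in fixed order
# N, CA, C, O, CEN, where CEN is the unified side-chain sphere. Coordinate
# matrices therefore have 5 * n_res rows.

PEP_ATOMS <- c("N", "CA", "C", "O", "CEN")

atom_residue_index <- function(n) rep(seq_len(n), each = 5L)
atom_names_vec <- function(n) rep(PEP_ATOMS, n)
atom_is_cen <- function(n) rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), n)

#' Create a flexible peptide chain
#'
#' The peptide is stored in torsion space (per-residue phi, psi, omega in
#' degrees) together with local-frame Cartesian coordinates rebuilt from the
#' torsions under ideal geometry. The local frame convention places the
#' first residue's N at the origin, CA on +x and C in the xy-plane.
#'
#' @param sequence One-letter amino-acid string (or character vector).
#' @param torsions Optional n x 3 matrix (phi, psi, omega) in degrees; when
#'   `NULL` the chain starts in the canonical extended conformation.
#' @param chain_id Single-letter chain identifier used on output.
#' @param resno Residue numbers to preserve on output (default 1..n).
#' @param anchor 1-based residue whose backbone triad roots the local
#'   frame (default 1). With the rigid transform held fixed, torsion edits
#'   fold the chain around this residue.
#' @return Object of class `pep_chain`.
#' @export
pep_chain <- function(sequence, torsions = NULL, chain_id = "B",
                      resno = NULL, anchor = 1L) {
  seq <- toupper(strsplit(paste(sequence, collapse = ""), "")[[1]])
  n <- length(seq)
  if (n < 1) stop("empty peptide sequence")
  info <- aa_lookup(seq)
  if (is.null(torsions)) {
    torsions <- cbind(phi = rep(135, n), psi = rep(-135, n),
                      omega = rep(180, n))
  }
  torsions <- as.matrix(torsions)
  if (nrow(torsions) != n || ncol(torsions) != 3) {
    stop("torsions must be an n x 3 matrix matching the sequence length")
  }
  defined <- matrix(TRUE, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  defined[1, "phi"] <- FALSE
  defined[n, c("psi", "omega")] <- FALSE
  defined[is.na(torsions)] <- FALSE
  colnames(torsions) <- c("phi", "psi", "omega")
  ch <- structure(list(
    seq = seq,
    tor = torsions,
    defined = defined,
    cen_dist = info$cen_dist,
    cen_rad = info$cen_rad,
    rama_class = rama_class_of(seq),
    chain_id = chain_id,
    resno = if (is.null(resno)) seq_len(n) else resno,
    anchor = as.integer(anchor),
    local = NULL,
    stale = TRUE
  ), class = "pep_chain")
  if (ch$anchor < 1 || ch$anchor > n) stop("anchor out of range")
  rebuild_chain(ch)
}

chain_length <- function(chain) length(chain$seq)

# fill undefined torsions with rebuild-safe conventions (phi1 unused,
# psi_n places the terminal carbonyl O, omega_n unused)
tor_filled <- function(chain) {
  tor <- chain$tor
  tor[is.na(tor[, 1]), 1] <- 135
  tor[is.na(tor[, 2]), 2] <- -135
  tor[is.na(tor[, 3]), 3] <- 180
  tor
}

#' Rebuild peptide Cartesian coordinates from torsions
#'
#' Sequential NeRF-style placement of N, CA, C from (phi, psi, omega) under
#' ideal bond lengths and angles; the carbonyl O and side-chain centroid
#' CEN are placed from local frames. Deterministic and idempotent.
#'
#' @param chain A `pep_chain`.
#' @param geometry Ideal geometry constants, see [ideal_geometry()].
#' @return The chain with `local` coordinates rebuilt.
#' @export
torsions_to_coords <- function(chain, geometry = ideal_geometry()) {
  rebuild_chain(chain, geometry)
}

rebuild_chain <- function(chain, geometry = ideal_geometry()) {
  n <- chain_length(chain)
  tor <- tor_filled(chain)
  und <- which(is.na(chain$tor[, 1]) & seq_len(n) > 1)
  if (length(und) > 0) {
    stop("undefined interior phi torsion at residue ", und[1])
  }
  xyz <- cpp_build_coords(tor, chain$cen_dist, as.numeric(geometry))
  a <- if (is.null(chain$anchor)) 1L else chain$anchor
  if (a > 1) {
    # re-root the local frame at the anchor residue's backbone triad
    row <- 5 * (a - 1) + 1
    xf <- frame_from_residue(xyz[row, ], xyz[row + 1, ], xyz[row + 2, ])
    xyz <- xform_apply(xform_inverse(xf), xyz)
  }
  rownames(xyz) <- paste0(atom_names_vec(n), atom_residue_index(n))
  chain$local <- xyz
  chain$stale <- FALSE
  chain
}

#' Re-root the peptide local frame at a new anchor residue
#'
#' @param chain A `pep_chain`.
#' @param anchor 1-based residue index.
#' @return The chain, rebuilt in the new anchor frame.
#' @export
set_anchor <- function(chain, anchor) {
  n <- chain_length(chain)
  if (anchor < 1 || anchor > n) stop("anchor out of range")
  chain$anchor <- as.integer(anchor)
  rebuild_chain(chain)
}

#' Set the canonical extended conformation
#'
#' Sets phi = +135, psi = -135 for every position and omega = 180 (trans),
#' then rebuilds coordinates.
#'
#' @param chain A `pep_chain`.
#' @return The extended chain.
#' @export
set_extended <- function(chain) {
  n <- chain_length(chain)
  chain$tor <- cbind(phi = rep(135, n), psi = rep(-135, n),
                     omega = rep(180, n))
  rebuild_chain(chain)
}

#' Replace peptide torsions
#'
#' @param chain A `pep_chain`.
#' @param torsions n x 3 replacement matrix (degrees).
#' @param rebuild Rebuild coordinates immediately (default); when `FALSE`
#'   the chain is flagged stale and cannot be scored until rebuilt.
#' @return Updated chain.
#' @export
set_torsions <- function(chain, torsions, rebuild = TRUE) {
  torsions <- as.matrix(torsions)
  stopifnot(nrow(torsions) == chain_length(chain), ncol(torsions) == 3)
  colnames(torsions) <- c("phi", "psi", "omega")
  chain$tor <- torsions
  if (rebuild) rebuild_chain(chain) else { chain$stale <- TRUE; chain }
}

#' @export
print.pep_chain <- function(x, ...) {
  cat("pep_chain:", paste(x$seq, collapse = ""),
      sprintf("(%d residues)\n", chain_length(x)))
  invisible(x)
}

# --- receptor ---------------------------------------------------------------

new_receptor <- function(coords, radii, is_cen, seq, resno, chain_id,
                         atom_names = NULL) {
  n <- length(seq)
  structure(list(
    coords = coords, radii = radii, is_cen = is_cen, seq = seq,
    resno = resno, chain_id = chain_id,
    atom_names = if (is.null(atom_names)) atom_names_vec(n) else atom_names,
    atom_res = atom_residue_index(n)
  ), class = "pep_receptor")
}

#' @export
print.pep_receptor <- function(x, ...) {
  cat("pep_receptor: chain", x$chain_id,
      sprintf("(%d residues, %d sites)\n", length(x$seq), nrow(x$coords)))
  invisible(x)
}

# --- complex pose -----------------------------------------------------------

#' Create a receptor-peptide complex pose
#'
#' @param receptor A `pep_receptor` (immutable during simulation).
#' @param peptide A `pep_chain`.
#' @param xform `rigid_xform` mapping peptide local coordinates into the
#'   receptor frame.
#' @param meta Optional named list of run metadata (anchor index, seeds...).
#' @return Object of class `complex_pose`.
#' @export
complex_pose <- function(receptor, peptide, xform = rigid_xform(),
                         meta = list()) {
  stopifnot(inherits(receptor, "pep_receptor"), inherits(peptide, "pep_chain"),
            inherits(xform, "rigid_xform"))
  structure(list(receptor = receptor, peptide = peptide, xform = xform,
                 meta = meta), class = "complex_pose")
}

#' World-frame peptide coordinates of a pose
#' @param pose A `complex_pose`.
#' @return (5 n) x 3 matrix of peptide site coordinates in the receptor frame.
#' @export
peptide_world_coords <- function(pose) {
  xform_apply(pose$xform, pose$peptide$local)
}

#' @export
print.complex_pose <- function(x, ...) {
  cat("complex_pose: receptor", x$receptor$chain_id, "+ peptide",
      paste(x$peptide$seq, collapse = ""), "\n")
  invisible(x)
}

#' Superpose the extended peptide on a native anchor residue
#'
#' Sets the pose's rigid-body transform so that the peptide's anchor residue
#' backbone (N, CA, C) is least-squares superposed on the same residue of the
#' native complex. Peptide torsions are unchanged; the anchor choice is
#' recorded in the pose metadata.
#'
#' @param pose Pose whose transform is to be set.
#' @param native_pose Reference pose supplying the anchor coordinates.
#' @param anchor_index 1-based peptide residue index, valid in both poses.
#' @return The pose with updated transform and `meta$anchor`.
#' @export
place_at_anchor <- function(pose, native_pose, anchor_index) {
  n <- chain_length(pose$peptide)
  if (anchor_index < 1 || anchor_index > n ||
      anchor_index > chain_length(native_pose$peptide)) {
    stop("anchor_index out of range")
  }
  rows <- 5 * (anchor_index - 1) + 1:3  # N, CA, C
  P <- pose$peptide$local[rows, , drop = FALSE]
  Q <- peptide_world_coords(native_pose)[rows, , drop = FALSE]
  pose$xform <- kabsch(P, Q)
  pose$meta$anchor <- anchor_index
  pose
}

# --- PDB I/O (via bio3d) ----------------------------------------------------

BACKBONE_SET <- c("N", "CA", "C", "O")

# per-residue extraction from a bio3d atom data.frame for one chain
extract_chain_sites <- function(atoms, chain, role) {
  sel <- atoms$chain == chain & atoms$type == "ATOM"
  atoms <- atoms[sel, , drop = FALSE]
  if (nrow(atoms) == 0) stop("chain '", chain, "' not found in PDB")
  # first altLoc only
  atoms <- atoms[atoms$alt %in% c("", " ", "A", NA), , drop = FALSE]
  key <- paste(atoms$resno, atoms$insert)
  keys <- unique(key)
  n <- length(keys)
  coords <- matrix(NA_real_, 5 * n, 3)
  seq1 <- character(n)
  resno <- integer(n)
  for (i in seq_len(n)) {
    ra <- atoms[key == keys[i], , drop = FALSE]
    resno[i] <- ra$resno[1]
    seq1[i] <- bio3d::aa321(ra$resid[1])
    for (k in 1:4) {
      row <- which(trimws(ra$elety) == BACKBONE_SET[k])
      if (length(row) == 0) {
        stop("missing backbone atom ", BACKBONE_SET[k], " in ", role,
             " residue ", ra$resid[1], " ", resno[i])
      }
      coords[5 * (i - 1) + k, ] <- c(ra$x[row[1]], ra$y[row[1]], ra$z[row[1]])
    }
    # CEN: geometric mean of side-chain heavy atoms if present, otherwise
    # the ideal extrapolated C-beta site
    sc <- ra[!(trimws(ra$elety) %in% c(BACKBONE_SET, "CEN")) &
               !grepl("^H", trimws(ra$elety)), , drop = FALSE]
    if (nrow(sc) > 0) {
      coords[5 * (i - 1) + 5, ] <- c(mean(sc$x), mean(sc$y), mean(sc$z))
    } else {
      bb <- coords[5 * (i - 1) + 1:3, ]
      info <- aa_lookup(seq1[i])
      coords[5 * (i - 1) + 5, ] <- bb[2, ] +
        cb_direction_r(bb[1, ], bb[2, ], bb[3, ]) * info$cen_dist
    }
  }
  list(coords = coords, seq = seq1, resno = resno)
}

# extrapolated C-beta unit direction (same construction as the C++ core)
cb_direction_r <- function(n, ca, c) {
  b <- ca - n; cc <- c - ca
  a <- c(b[2] * cc[3] - b[3] * cc[2],
         b[3] * cc[1] - b[1] * cc[3],
         b[1] * cc[2] - b[2] * cc[1])
  d <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  d / sqrt(sum(d^2))
}

torsions_from_backbone <- function(coords, n) {
  N <- coords[5 * (seq_len(n) - 1) + 1, , drop = FALSE]
  CA <- coords[5 * (seq_len(n) - 1) + 2, , drop = FALSE]
  C <- coords[5 * (seq_len(n) - 1) + 3, , drop = FALSE]
  O <- coords[5 * (seq_len(n) - 1) + 4, , drop = FALSE]
  tor <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
  for (i in seq_len(n)) {
    if (i > 1) tor[i, 1] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    if (i < n) {
      tor[i, 2] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      tor[i, 3] <- dihedral_angle(CA[i, ], C[i, ], N[i + 1, ], CA[i + 1, ])
    }
  }
  # surrogate terminal psi from the carbonyl O so that O_n is reproduced on
  # rebuild; remains flagged undefined
  tor[n, 2] <- wrap_angle(dihedral_angle(N[n, ], CA[n, ], C[n, ], O[n, ]) + 180)
  tor[n, 3] <- 180
  tor
}

frame_from_residue <- function(n, ca, c) {
  ex <- (ca - n); ex <- ex / sqrt(sum(ex^2))
  v <- (c - n); v <- v - sum(v * ex) * ex
  ey <- v / sqrt(sum(v^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  rigid_xform(cbind(ex, ey, ez), n)
}

#' Read a receptor-peptide complex from a PDB file
#'
#' Both chains must be present with complete backbones. Side-chain centroid
#' pseudo-atoms (CEN) are placed at the geometric mean of side-chain heavy
#' atoms when side chains are present, otherwise at the ideal extrapolated
#' C-beta site. Peptide torsions are computed from the coordinates; the
#' as-read coordinates are preserved in the pose (re-idealization happens
#' only when torsions are edited and coordinates rebuilt).
#'
#' @param path PDB file path.
#' @param receptor_chain,peptide_chain Single-letter chain identifiers.
#' @return A `complex_pose`.
#' @export
read_pdb <- function(path, receptor_chain, peptide_chain) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  rec <- extract_chain_sites(atoms, receptor_chain, "receptor")
  pep <- extract_chain_sites(atoms, peptide_chain, "peptide")
  n <- length(pep$seq)
  if (n < 3) stop("peptide must have at least 3 residues, found ", n)
  m <- length(rec$seq)
  rec_info <- aa_lookup(rec$seq)
  radii <- rep(BACKBONE_RADIUS, 5 * m)
  radii[atom_is_cen(m)] <- rec_info$cen_rad
  receptor <- new_receptor(rec$coords, radii, atom_is_cen(m), rec$seq,
                           rec$resno, receptor_chain)
  tor <- torsions_from_backbone(pep$coords, n)
  chain <- pep_chain(pep$seq, torsions = tor, chain_id = peptide_chain,
                     resno = pep$resno)
  # express the as-read coordinates in the residue-1 local frame so they are
  # preserved exactly; a rebuild (after any torsion edit) re-idealizes them
  xf <- frame_from_residue(pep$coords[1, ], pep$coords[2, ], pep$coords[3, ])
  chain$local <- xform_apply(xform_inverse(xf), pep$coords)
  rownames(chain$local) <- paste0(atom_names_vec(n), atom_residue_index(n))
  complex_pose(receptor, chain, xf, meta = list(source = path))
}

#' Write a complex pose to a PDB file
#'
#' Writes standard ATOM records for receptor then peptide backbone atoms.
#' CEN pseudo-atoms (atom name `CEN`, element X) are written only when
#' `write_cen = TRUE`.
#'
#' @param pose A `complex_pose`.
#' @param path Output file path.
#' @param write_cen Include side-chain centroid pseudo-atoms.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(pose, path, write_cen = FALSE) {
  pep <- pose$peptide
  n <- chain_length(pep)
  if (n == 0) stop("pose has an empty peptide")
  rec <- pose$receptor
  m <- length(rec$seq)
  keep_r <- if (write_cen) rep(TRUE, 5 * m) else !rec$is_cen
  keep_p <- if (write_cen) rep(TRUE, 5 * n) else !atom_is_cen(n)
  pw <- peptide_world_coords(pose)
  coords <- rbind(rec$coords[keep_r, , drop = FALSE],
                  pw[keep_p, , drop = FALSE])
  elety <- c(rec$atom_names[keep_r], atom_names_vec(n)[keep_p])
  res_r <- rec$resno[rec$atom_res][keep_r]
  res_p <- pep$resno[atom_residue_index(n)][keep_p]
  resid <- c(bio3d::aa123(rec$seq)[rec$atom_res][keep_r],
             bio3d::aa123(pep$seq)[atom_residue_index(n)][keep_p])
  chain <- c(rep(rec$chain_id, sum(keep_r)), rep(pep$chain_id, sum(keep_p)))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                   resno = c(res_r, res_p), resid = resid,
                   eleno = seq_len(nrow(coords)), elety = elety,
                   chain = chain, o = rep(1, nrow(coords)),
                   b = rep(0, nrow(coords)))
  invisible(path)
}
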