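# Synthetic, fully self-contained test systems: a rigid groove receptor
# built from two helical walls, a planted native peptide, extended and
# perturbed starting structures, and fragment source sets guaranteed to
# contain near-native windows. Fixture realism is not a goal; fixtures
# exercise the protocol's mechanics and the planted-native recovery
# property without any external data.

#' Specification of a toy complex
#'
#' @param length Peptide length, 5-13 residues.
#' @param ss Peptide secondary-structure type: `"helix"`, `"strand"` or
#'   `"coil"`.
#' @param seed Seed recorded in all derived fixtures.
#' @param sequence Optional one-letter peptide sequence; drawn from a
#'   small/medium-residue alphabet when `NULL`.
#' @param groove_width Wall separation in Angstrom; `NA` auto-calibrates
#'   (smallest clash-free separation of lowest energy).
#' @param wall_len Wall helix length in residues (default `length + 4`).
#' @return Object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(length = 8, ss = c("helix", "strand", "coil"),
                             seed = 1, sequence = NULL, groove_width = NA,
                             wall_len = length + 6) {
  ss <- match.arg(ss)
  if (length < 5 || length > 13) stop("peptide length must be in [5, 13]")
  structure(list(length = length, ss = ss, seed = seed, sequence = sequence,
                 groove_width = groove_width, wall_len = wall_len),
            class = "toy_complex_spec")
}

TOY_ALPHABET <- c("A", "S", "L", "T", "V", "N")

toy_ss_torsions <- function(ss, n) {
  if (ss == "helix") {
    cbind(phi = rep(-60, n), psi = rep(-45, n), omega = rep(180, n))
  } else if (ss == "strand") {
    cbind(phi = rep(-120, n), psi = rep(120, n), omega = rep(180, n))
  } else {
    # per-residue draws from the favored Ramachandran boxes
    box <- sample(c("helix", "sheet"), n, replace = TRUE)
    phi <- ifelse(box == "helix", runif(n, -155, -45), runif(n, -175, -65))
    psi <- ifelse(box == "helix", runif(n, -75, -5), runif(n, 85, 175))
    cbind(phi = phi, psi = psi, omega = rep(180, n))
  }
}

# rotation carrying unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate 180 degrees about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    perp <- perp - sum(perp * a) * a
    return(rot_axis_angle(perp, 180))
  }
  rot_axis_angle(v, acos(max(-1, min(1, c_))) * 180 / pi)
}

# transform orienting a chain's CA trace along +y, centered at the origin
orientation_along_y <- function(local, n) {
  ca <- local[5 * (seq_len(n) - 1) + 2, , drop = FALSE]
  # smooth the helical wobble before fitting the axis
  k <- min(4, n)
  mid <- t(vapply(seq_len(n - k + 1), function(i) {
    colMeans(ca[i:(i + k - 1), , drop = FALSE])
  }, numeric(3)))
  axis <- prcomp(mid)$rotation[, 1]
  if (sum(axis * (ca[n, ] - ca[1, ])) < 0) axis <- -axis
  R <- rotation_between(axis, c(0, 1, 0))
  center <- colMeans(ca)
  rigid_xform(R, as.numeric(-R %*% center))
}

toy_wall_chain <- function(wall_len) {
  pep_chain(paste(rep("A", wall_len), collapse = ""),
            torsions = cbind(rep(-60, wall_len), rep(-45, wall_len),
                             rep(180, wall_len)), chain_id = "A")
}

build_toy_receptor <- function(spec, sep) {
  wall <- toy_wall_chain(spec$wall_len)
  nw <- spec$wall_len
  xf <- orientation_along_y(wall$local, nw)
  a <- sweep(xform_apply(xf, wall$local), 2, c(sep / 2, 0, 0), "+")
  flip <- rot_axis_angle(c(0, 1, 0), 180)
  b <- sweep(xform_apply(xf, wall$local) %*% t(flip), 2, c(-sep / 2, 0, 0),
             "+")
  coords <- rbind(a, b)
  seq <- rep("A", 2 * nw)
  info <- aa_lookup(seq)
  radii <- rep(BACKBONE_RADIUS, 10 * nw)
  radii[atom_is_cen(2 * nw)] <- info$cen_rad
  new_receptor(coords, radii, atom_is_cen(2 * nw), seq, seq_len(2 * nw), "A")
}


# coordinate-wise translation polish of the peptide placement; with
# `clash_free` only e_rep = 0 placements with backbone clearance are ever
# accepted
polish_translation <- function(pose, weights, span = 2, step = 0.1,
                               sweeps = 2, clash_free = TRUE) {
  sys <- build_sys(pose)
  wvec <- weights_vec(weights)
  tor <- tor_filled(pose$peptide)
  world <- peptide_world_coords(pose)
  n <- chain_length(pose$peptide)
  shift <- c(0, 0, 0)
  e_of <- function(off) {
    w <- sweep(world, 2, off, "+")
    b <- cpp_score_xyz(sys, w, tor, wvec)
    if (clash_free && b[["e_rep"]] > 1e-9) Inf else b[["e_total"]]
  }
  best_e <- e_of(shift)
  for (sw in seq_len(sweeps)) {
    for (axis in 1:3) {
      for (o in seq(-span, span, by = step)) {
        trial <- shift
        trial[axis] <- trial[axis] + o
        e <- e_of(trial)
        if (e < best_e - 1e-12) { best_e <- e; shift <- trial }
      }
    }
    span <- span / 2
  }
  pose$xform$t <- pose$xform$t + shift
  pose
}

# roll the peptide about the groove axis (y) through its own centroid
apply_roll <- function(xform, roll_deg, center) {
  rot <- rot_axis_angle(c(0, 1, 0), roll_deg)
  rigid_xform(reorthonormalize(rot %*% xform$R),
              as.numeric(rot %*% (xform$t - center)) + center)
}

polish_roll <- function(pose, weights, span = 15, step = 2.5,
                        clash_free = TRUE) {
  e_of <- function(p) {
    b <- score_pose(p, weights)
    if (clash_free && b$e_rep > 1e-9) Inf else b$e_total
  }
  best_e <- e_of(pose)
  center <- colMeans(peptide_world_coords(pose))
  for (roll in seq(-span, span, by = step)) {
    trial <- pose
    trial$xform <- apply_roll(pose$xform, roll, center)
    e <- e_of(trial)
    if (e < best_e - 1e-12) { best_e <- e; pose <- trial }
  }
  pose
}

# Design the receptor pocket around the planted peptide: each wall
# residue's side-chain centroid slides along its fixed C-beta direction,
# and its size class (small/medium/large; the wall residue type is
# re-assigned accordingly) is chosen jointly, maximizing attraction to the
# peptide subject to a clash-free gap >= min_gap. Centroids pointing into
# the groove become fat contact knobs, clashing ones retract and slim
# down, producing a pocket complementary to the native peptide. The
# receptor is immutable afterwards.
ADAPT_CLASSES <- data.frame(aa = c("A", "N", "W"), rad = c(1.4, 1.8, 2.2))

adapt_receptor_to_peptide <- function(receptor, pep_world, pep_radii,
                                      min_gap = 0.05) {
  m <- length(receptor$seq)
  Ls <- seq(0.3, 6, by = 0.05)
  for (j in seq_len(m)) {
    ca <- receptor$coords[5 * (j - 1) + 2, ]
    cen_row <- 5 * (j - 1) + 5
    cen <- receptor$coords[cen_row, ]
    dir <- cen - ca
    dir <- dir / sqrt(sum(dir^2))
    pos <- outer(Ls, dir) + rep(ca, each = length(Ls))
    dmat <- sqrt(pmax(outer(rowSums(pos^2), rowSums(pep_world^2), "+") -
                        2 * pos %*% t(pep_world), 0))
    pick <- NULL
    for (k in seq_len(nrow(ADAPT_CLASSES))) {
      rc <- ADAPT_CLASSES$rad[k]
      gap <- dmat - rep(pep_radii + rc, each = length(Ls))
      min_gap_l <- apply(gap, 1, min)
      adm <- min_gap_l >= min_gap
      # never tunnel through the peptide: admissible positions end at the
      # first clash beyond the first admissible stretch
      first_adm <- match(TRUE, adm)
      if (!is.na(first_adm)) {
        stop_at <- match(TRUE, !adm & seq_along(adm) > first_adm)
        if (!is.na(stop_at)) adm[stop_at:length(adm)] <- FALSE
      }
      att_l <- -rowSums((abs(gap) < 2) * (1 - (pmin(abs(gap), 2) / 2)^2))
      cand <- if (any(adm) && min(att_l[adm]) < 0) {
        list(L = Ls[adm][which.min(att_l[adm])], att = min(att_l[adm]),
             rc = rc, aa = ADAPT_CLASSES$aa[k], ok = TRUE)
      } else if (any(adm)) {
        # no native contact from this ray: retract into the backbone
        list(L = 0.3, att = 0.5 - 0.01 * rc, rc = rc,
             aa = ADAPT_CLASSES$aa[k], ok = TRUE)
      } else {
        list(L = Ls[which.max(min_gap_l)], att = 1, rc = rc,
             aa = ADAPT_CLASSES$aa[k], ok = FALSE)
      }
      if (is.null(pick) || (cand$ok && !pick$ok) ||
          (cand$ok == pick$ok && cand$att < pick$att)) {
        pick <- cand
      }
    }
    receptor$coords[cen_row, ] <- ca + pick$L * dir
    receptor$radii[cen_row] <- pick$rc
    receptor$seq[j] <- pick$aa
  }
  receptor
}

#' Build a planted-native toy complex
#'
#' The receptor is two parallel rigid helical walls along the y-axis whose
#' gap forms a V-shaped groove; the peptide is built with canonical
#' torsions for the requested secondary-structure type, oriented along the
#' groove, and settled into it by a deterministic grid search over wall
#' separation, axial roll and translation that minimizes the total energy
#' subject to zero repulsive energy. Peptide side-chain centroids are then
#' prepacked (and the placement re-polished) so that the native satisfies
#' e_rep = 0 and e_interface < 0 and is a local minimum under rigid-body
#' translations.
#'
#' @param spec A [toy_complex_spec()].
#' @param weights A [score_weights()] used for calibration.
#' @return The native `complex_pose` (with `meta$spec`).
#' @export
make_native_complex <- function(spec, weights = score_weights()) {
  set.seed(spec$seed)
  n <- spec$length
  best_pose <- NULL
  # a few peptide sequences are geometrically impossible to seat without
  # residual centroid clashes; draw deterministically until one clears
  for (draw in 1:6) {
    sequence <- spec$sequence
    if (is.null(sequence)) {
      sequence <- paste(sample(TOY_ALPHABET, n, replace = TRUE),
                        collapse = "")
    }
    pose <- build_native_for_sequence(spec, sequence, weights)
    rep_now <- score_pose(pose, weights)$e_rep
    if (is.null(best_pose) || rep_now < best_pose$rep) {
      best_pose <- list(pose = pose, rep = rep_now)
    }
    if (rep_now < 1e-9 || !is.null(spec$sequence)) break
  }
  if (best_pose$rep > 1e-9) {
    warning("native placement retains residual clashes")
  }
  best_pose$pose
}

build_native_for_sequence <- function(spec, sequence, weights) {
  n <- spec$length
  chain <- pep_chain(sequence, torsions = toy_ss_torsions(spec$ss, n),
                     chain_id = "B")
  xf0 <- orientation_along_y(chain$local, n)
  seps <- if (is.na(spec$groove_width)) c(13, 14) else
    spec$groove_width
  # The peptide sits midway between the walls with its centroids buried
  # against the wall backbone; for each candidate separation and axial
  # roll the receptor centroids are adapted (clashing ones retract,
  # groove-facing ones grow into contact knobs) and the deepest adapted
  # pocket wins.
  pep_rad <- rep(BACKBONE_RADIUS, 5 * n)
  pep_rad[atom_is_cen(n)] <- chain$cen_rad
  # construction-grade weights: a much harsher repulsion steers the
  # placement search to deep but strictly clash-free geometries
  w_design <- weights
  w_design$w_rep <- 10 * weights$w_rep
  # enumerate candidate placements in the groove (raw contact energy, no
  # pocket yet), best first
  cands <- list()
  for (sep in seps) {
    receptor <- build_toy_receptor(spec, sep)
    for (roll in seq(0, 330, by = 30)) {
      xf1 <- apply_roll(xf0, roll, c(0, 0, 0))
      for (z in seq(-1, 1, by = 0.5)) {
        xf2 <- xf1
        xf2$t <- xf1$t + c(0, 0, z)
        pose <- complex_pose(receptor, chain, xf2)
        b <- score_pose(pose, w_design)
        cands[[length(cands) + 1]] <- list(pose = pose, sep = sep,
                                           e_total = b$e_total)
      }
    }
  }
  cands <- cands[order(vapply(cands, function(x) x$e_total, 0))]
  # design the pocket at the best placement that can be made strictly
  # clash-free: adapt the receptor, prepack the peptide centroids and
  # re-polish, backing the peptide out of the groove a touch if needed
  # deterministically relieve each residual clashing pair: clashing
  # receptor centroids re-seat along their rays, clashing peptide
  # centroids re-seat along theirs; returns NULL if a backbone-backbone
  # clash (unfixable by centroid surgery) remains
  clear_residual <- function(pose) {
    n_at <- 5 * n
    for (iter in 1:25) {
      b <- score_pose(pose, weights)
      if (b$e_rep < 1e-9) return(pose)
      pw <- peptide_world_coords(pose)
      rcoo <- pose$receptor$coords
      rrad <- pose$receptor$radii
      prad <- rep(BACKBONE_RADIUS, n_at)
      prad[atom_is_cen(n)] <- pose$peptide$cen_rad
      pcen <- atom_is_cen(n)
      rcen <- pose$receptor$is_cen
      res_of <- atom_residue_index(n)
      fixed <- FALSE
      # cross-chain clashes
      d2 <- outer(rowSums(pw^2), rowSums(rcoo^2), "+") - 2 * pw %*% t(rcoo)
      gap <- sqrt(pmax(d2, 0)) - outer(prad, rrad, "+")
      idx <- which(gap < -1e-9, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        i <- idx[1, 1]; j <- idx[1, 2]
        if (rcen[j]) {
          # re-seat this receptor centroid anywhere clear on its ray
          jr <- pose$receptor$atom_res[j]
          ca <- rcoo[5 * (jr - 1) + 2, ]
          dir <- rcoo[j, ] - ca
          dir <- dir / sqrt(sum(dir^2))
          for (L in seq(0.3, 6, by = 0.05)) {
            pos <- ca + L * dir
            g <- sqrt(rowSums(sweep(pw, 2, pos)^2)) - (prad + rrad[j])
            if (min(g) >= 0.01) {
              pose$receptor$coords[j, ] <- pos
              fixed <- TRUE
              break
            }
          }
          if (!fixed) {  # slim it down and hug the backbone
            pose$receptor$radii[j] <- 1.4
            pose$receptor$coords[j, ] <- ca + 0.3 * dir
            fixed <- TRUE
          }
        } else if (pcen[i]) {
          r <- res_of[i]
          ca <- pw[5 * (r - 1) + 2, ]
          dir <- (pw[i, ] - ca) / pose$peptide$cen_dist[r]
          others <- setdiff(seq_len(n_at), which(abs(res_of - r) < 3))
          for (d in seq(0.05, 4.5, by = 0.05)) {
            pos <- ca + d * dir
            g1 <- sqrt(rowSums(sweep(rcoo, 2, pos)^2)) - (rrad + prad[i])
            g2 <- sqrt(rowSums(sweep(pw[others, , drop = FALSE], 2,
                                     pos)^2)) - (prad[others] + prad[i])
            if (min(g1) >= 0.01 && min(g2) >= 0.01) {
              pose$peptide$cen_dist[r] <- d
              pose$peptide <- rebuild_chain(pose$peptide)
              fixed <- TRUE
              break
            }
          }
          if (!fixed) return(NULL)
        } else {
          return(NULL)  # backbone-backbone interpenetration
        }
      } else {
        # intra-peptide clash (always involves a centroid): re-seat it
        sep_ok <- abs(outer(res_of, res_of, "-")) >= 3
        cen_pair <- outer(pcen, pcen, "|")
        d2i <- outer(rowSums(pw^2), rowSums(pw^2), "+") - 2 * pw %*% t(pw)
        gi <- sqrt(pmax(d2i, 0)) - outer(prad, prad, "+")
        gi[!sep_ok | !cen_pair | !upper.tri(gi)] <- Inf
        ij <- which(gi < -1e-9, arr.ind = TRUE)
        if (nrow(ij) == 0) return(pose)
        i <- if (pcen[ij[1, 1]]) ij[1, 1] else ij[1, 2]
        r <- res_of[i]
        ca <- pw[5 * (r - 1) + 2, ]
        dir <- (pw[i, ] - ca) / pose$peptide$cen_dist[r]
        others <- setdiff(seq_len(n_at), which(abs(res_of - r) < 3))
        for (d in seq(0.05, 4.5, by = 0.05)) {
          pos <- ca + d * dir
          g1 <- sqrt(rowSums(sweep(rcoo, 2, pos)^2)) - (rrad + prad[i])
          g2 <- sqrt(rowSums(sweep(pw[others, , drop = FALSE], 2,
                                   pos)^2)) - (prad[others] + prad[i])
          if (min(g1) >= 0.01 && min(g2) >= 0.01) {
            pose$peptide$cen_dist[r] <- d
            pose$peptide <- rebuild_chain(pose$peptide)
            fixed <- TRUE
            break
          }
        }
        if (!fixed) return(NULL)
      }
      if (!fixed) return(NULL)
    }
    NULL
  }

  clear_placement <- function(start_pose) {
    best_effort <- NULL
    for (off in c(0, 0.15, -0.15, 0.3, -0.3, 0.5, -0.5)) {
      pose <- start_pose
      pose$xform$t[3] <- pose$xform$t[3] + off
      pose$receptor <- adapt_receptor_to_peptide(pose$receptor,
                                                 peptide_world_coords(pose),
                                                 pep_rad)
      for (round in 1:3) {
        pose <- prepack(pose, w_design)
        pose <- polish_translation(pose, w_design, span = 1.0, step = 0.05,
                                   sweeps = 2, clash_free = (round > 1))
        pose$receptor <- adapt_receptor_to_peptide(
          pose$receptor, peptide_world_coords(pose), pep_rad,
          min_gap = 0.05 * round)
        pose <- prepack(pose, w_design)
        if (score_pose(pose, weights)$e_rep < 1e-9) break
      }
      rep_now <- score_pose(pose, weights)$e_rep
      if (rep_now < 1e-9) return(pose)
      cleared <- clear_residual(pose)
      if (!is.null(cleared)) return(cleared)
      if (is.null(best_effort) || rep_now < best_effort$rep) {
        best_effort <- list(pose = pose, rep = rep_now)
      }
    }
    best_effort$pose
  }
  pose <- NULL
  fallback <- NULL
  for (k in seq_len(min(8, length(cands)))) {
    trial <- clear_placement(cands[[k]]$pose)
    rep_k <- score_pose(trial, weights)$e_rep
    if (rep_k < 1e-9) {
      pose <- trial
      sep_used <- cands[[k]]$sep
      break
    }
    if (is.null(fallback) || rep_k < fallback$rep) {
      fallback <- list(pose = trial, rep = rep_k, sep = cands[[k]]$sep)
    }
  }
  if (is.null(pose)) {
    pose <- fallback$pose
    sep_used <- fallback$sep
  }
  pose <- polish_translation(pose, weights, span = 0.3, step = 0.05,
                             sweeps = 1)
  pose$meta$spec <- spec
  pose$meta$groove_width <- sep_used
  pose
}

#' Build the extended starting structure
#'
#' Sets the peptide to the canonical extended conformation (+135/-135) and
#' superposes it on a randomly chosen anchor residue of the native complex;
#' the anchor index is recorded in the pose metadata.
#'
#' @param native Native pose from [make_native_complex()].
#' @param anchor `"random"` or a 1-based residue index.
#' @param seed Seed for the anchor choice.
#' @return The starting `complex_pose`.
#' @export
make_start_structure <- function(native, anchor = "random", seed = 1) {
  set.seed(seed)
  n <- chain_length(native$peptide)
  idx <- if (identical(anchor, "random")) sample.int(n, 1) else
    as.integer(anchor)
  chain <- set_anchor(set_extended(native$peptide), idx)
  pose <- complex_pose(native$receptor, chain, rigid_xform(),
                       meta = native$meta)
  pose <- place_at_anchor(pose, native, idx)
  pose$meta$start_seed <- seed
  pose
}

#' Perturb the rigid-body orientation of a starting structure
#'
#' Applies a random Gaussian rigid-body perturbation of scales 3 Angstrom
#' and 30 degrees (robustness starts); peptide torsions are unchanged.
#'
#' @param start Starting pose.
#' @param seed Seed.
#' @param trans_sigma,rot_sigma Perturbation scales.
#' @return The perturbed pose.
#' @export
make_perturbed_start <- function(start, seed = 1, trans_sigma = 3,
                                 rot_sigma = 30) {
  set.seed(seed)
  centroid <- colMeans(peptide_world_coords(start))
  start$xform <- random_start_perturbation(start$xform, trans_sigma,
                                           rot_sigma, center = centroid)
  start$meta$perturb_seed <- seed
  start
}

COIL_BINS <- matrix(c(-140, 40, 60, 50, -70, -120, -100, 10),
                    ncol = 2, byrow = TRUE)

# one synthetic monomer: alternating H/E/C segments with jittered canonical
# torsions
toy_source_torsions <- function(n_res, seg_min = 10, seg_max = 16,
                                jitter = 8) {
  tor <- NULL
  types <- character(0)
  kinds <- c("H", "E", "C")
  k <- sample.int(3, 1)
  while (is.null(tor) || nrow(tor) < n_res) {
    len <- sample(seg_min:seg_max, 1)
    kind <- kinds[(k - 1) %% 3 + 1]
    k <- k + 1
    seg <- switch(kind,
      H = cbind(rep(-60, len), rep(-45, len)),
      E = cbind(rep(-120, len), rep(120, len)),
      C = COIL_BINS[sample.int(nrow(COIL_BINS), len, replace = TRUE), ,
                    drop = FALSE])
    seg <- seg + matrix(runif(2 * len, -jitter, jitter), len, 2)
    tor <- rbind(tor, cbind(seg, rep(180, len)))
    types <- c(types, rep(kind, len))
  }
  tor <- tor[seq_len(n_res), , drop = FALSE]
  colnames(tor) <- c("phi", "psi", "omega")
  tor
}

#' Generate a synthetic fragment source set
#'
#' Synthetic monomer chains (40-60 residues) with mixed secondary-structure
#' segments. The first sources carry an exact copy of the planted peptide's
#' interior torsions, guaranteeing near-native windows for every fragment
#' length in use.
#'
#' @param spec The [toy_complex_spec()] of the target complex.
#' @param n_sources Number of source chains (default 20).
#' @param seed Seed (default: the spec seed).
#' @param out_dir Optional directory to write the sources as PDB files.
#' @return List of `frag_source` objects.
#' @export
make_fragment_source_set <- function(spec, n_sources = 20,
                                     seed = spec$seed, out_dir = NULL) {
  native <- make_native_complex(spec)
  native_tor <- native$peptide$tor
  native_tor[1, 1] <- native_tor[2, 1]       # fill flagged terminals
  native_tor[nrow(native_tor), 2:3] <- c(native_tor[2, 2], 180)
  set.seed(seed)
  sources <- vector("list", n_sources)
  for (i in seq_len(n_sources)) {
    n_res <- sample(40:60, 1)
    tor <- toy_source_torsions(n_res)
    if (i %% 5 == 1) {
      # plant the native torsion block at a fixed interior position
      at <- 3:(2 + nrow(native_tor))
      tor[at, ] <- native_tor
    }
    seq <- sample(AA_TABLE$aa, n_res, replace = TRUE)
    # torsions at the termini are undefined, as in a real structure
    tor[1, 1] <- NA
    tor[n_res, 2:3] <- NA
    sources[[i]] <- new_frag_source(sprintf("toy_src_%02d", i), seq, tor)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (src in sources) {
      write_source_pdb(src, file.path(out_dir, paste0(src$id, ".pdb")))
    }
  }
  sources
}

#' Write a fragment source chain as a (backbone-only) PDB file
#' @param src A `frag_source`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_source_pdb <- function(src, path) {
  tor <- src$tor
  tor[is.na(tor[, 1]), 1] <- 135
  tor[is.na(tor[, 2]), 2] <- -135
  tor[is.na(tor[, 3]), 3] <- 180
  chain <- pep_chain(paste(src$seq, collapse = ""), torsions = tor,
                     chain_id = "A")
  n <- chain_length(chain)
  keep <- !atom_is_cen(n)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(chain$local[keep, ])),
                   resno = atom_residue_index(n)[keep],
                   resid = bio3d::aa123(chain$seq)[atom_residue_index(n)][keep],
                   eleno = seq_len(sum(keep)),
                   elety = atom_names_vec(n)[keep],
                   chain = rep("A", sum(keep)), o = rep(1, sum(keep)),
                   b = rep(0, sum(keep)))
  invisible(path)
}

#' Convenience bundle: native, start, fragments for a toy run
#'
#' @param spec A [toy_complex_spec()].
#' @param n_sources Fragment sources.
#' @return List: `native`, `start`, `sources`, `frags` (picked library),
#'   `ss_pred`.
#' @export
make_toy_system <- function(spec = toy_complex_spec(), n_sources = 24) {
  native <- make_native_complex(spec)
  start <- make_start_structure(native, seed = spec$seed)
  sources <- make_fragment_source_set(spec, n_sources = n_sources)
  ss_true <- c(helix = "H", strand = "E", coil = "C")[[spec$ss]]
  probs <- matrix(0.1, chain_length(native$peptide), 3,
                  dimnames = list(NULL, c("H", "E", "C")))
  probs[, ss_true] <- 0.8
  ss_pred <- ss_prediction(probs)
  lengths <- if (spec$length >= 9) c(3, 5, 9) else c(3, 5)
  pool <- unlist(lapply(lengths, function(L) {
    extract_candidate_windows(sources, L)
  }), recursive = FALSE)
  frags <- pick_fragments(paste(native$peptide$seq, collapse = ""), ss_pred,
                          pool)
  list(native = native, start = start, sources = sources, frags = frags,
       ss_pred = ss_pred)
}
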