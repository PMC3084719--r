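# Shared fixtures: built once per test run. The toy system uses a fixed
# spec so every test file sees the same planted complex.

toy_cache <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(toy_cache$sys)) {
    toy_cache$sys <- suppressWarnings(
      make_toy_system(toy_complex_spec(length = 8, ss = "helix", seed = 5)))
  }
  toy_cache$sys
}

# small free-standing chain used by kinematics/move tests
test_chain <- function(seq = "AKLAELAK", tor = NULL) {
  pepdock:::pep_chain(seq, torsions = tor)
}

helix_torsions <- function(n) {
  cbind(phi = rep(-60, n), psi = rep(-45, n), omega = rep(180, n))
}

# Independent oracle for the CA(i)->CA(i+1) distance of an ideal trans
# backbone: the CA-C-N-CA unit is planar for omega = 180, so the distance
# follows from the three bond lengths and two bond angles alone.
oracle_ca_ca_distance <- function(geom = ideal_geometry()) {
  ca1 <- c(0, 0)
  cc <- c(geom[["ca_c"]], 0)
  # angle CA-C-N opens away from CA1
  a1 <- (180 - geom[["ang_ca_c_n"]]) * pi / 180
  nn <- cc + geom[["c_n"]] * c(cos(a1), sin(a1))
  # trans omega: CA2 on the opposite side, angle C-N-CA2
  dir_cn <- (nn - cc) / sqrt(sum((nn - cc)^2))
  a2 <- (180 - geom[["ang_c_n_ca"]]) * pi / 180
  rot <- matrix(c(cos(-a2), -sin(-a2), sin(-a2), cos(-a2)), 2, 2,
                byrow = TRUE)
  ca2 <- nn + geom[["n_ca"]] * as.numeric(rot %*% dir_cn)
  sqrt(sum((ca2 - ca1)^2))
}

# independent O(n^2) oracle over the same pair rules
oracle_score_acceptance <- function(pose, weights) {
  n <- chain_length(pose$peptide)
  pw <- peptide_world_coords(pose)
  rc <- pose$receptor$coords
  prad <- rep(pepdock:::BACKBONE_RADIUS, 5 * n)
  prad[pepdock:::atom_is_cen(n)] <- pose$peptide$cen_rad
  pcen <- pepdock:::atom_is_cen(n)
  res <- pepdock:::atom_residue_index(n)
  pair <- function(d, r0) {
    rep_ <- if (d < r0) weights$w_rep * ((r0 - d) / r0)^2 else 0
    u <- (d - r0) / 2
    att <- if (abs(u) < 1) -weights$w_att * (1 - u^2) else 0
    c(rep_, att)
  }
  e_rep <- 0; e_att <- 0; e_int <- 0; e_pep <- 0
  for (i in seq_len(5 * n - 1)) {
    for (j in (i + 1):(5 * n)) {
      if (!(pcen[i] || pcen[j])) next
      if (abs(res[i] - res[j]) < 3) next
      pe <- pair(sqrt(sum((pw[i, ] - pw[j, ])^2)), prad[i] + prad[j])
      e_rep <- e_rep + pe[1]; e_att <- e_att + pe[2]
      e_pep <- e_pep + sum(pe)
    }
  }
  for (i in seq_len(5 * n)) {
    for (j in seq_len(nrow(rc))) {
      pe <- pair(sqrt(sum((pw[i, ] - rc[j, ])^2)),
                 prad[i] + pose$receptor$radii[j])
      e_rep <- e_rep + pe[1]; e_att <- e_att + pe[2]
      e_int <- e_int + sum(pe)
    }
  }
  cls <- c("generic", "glycine", "proline")
  mask <- pose$peptide$defined[, "phi"] & pose$peptide$defined[, "psi"]
  e_rama <- sum(weights$w_rama * vapply(which(mask), function(r) {
    rama_energy(pose$peptide$tor[r, 1], pose$peptide$tor[r, 2],
                cls[pose$peptide$rama_class[r] + 1])
  }, 0))
  list(e_rep = e_rep, e_att = e_att, e_rama = e_rama,
       e_total = e_rep + e_att + e_rama, e_interface = e_int,
       e_peptide = e_pep + e_rama + e_int)
}

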