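# Monte-Carlo move generators and the Metropolis acceptance rule.
# These are the reference (R-level) implementations of the moves; the inner
# simulation loops execute the same moves in compiled code, drawing from
# R's RNG so trajectories are reproducible from a single seed.

#' Monte-Carlo move schedule
#'
#' Probabilities and magnitudes of the backbone and rigid-body moves of the
#' low-resolution stage: 60% of backbone moves are phi/psi perturbations
#' (split between small and shear), the rest are fragment insertions with a
#' 30% / 7.5% / 2.5% trimer / pentamer / nonamer mixture; nonamers apply
#' only to peptides of nine or more residues.
#'
#' @param p_torsion Probability of a small/shear torsion move.
#' @param p_trimer,p_pentamer,p_nonamer Fragment-insertion probabilities.
#' @param small_frac Fraction of torsion moves that are small (vs shear).
#' @param torsion_mag Maximum phi/psi perturbation (degrees) at the
#'   reference temperature 2.0; the effective magnitude scales linearly
#'   with T (`torsion_mag * T / 2`).
#' @param trans_mag Mean rigid-body translation magnitude (Angstrom).
#' @param rot_mag Mean rigid-body rotation magnitude (degrees).
#' @param t_rama Temperature of the Ramachandran Metropolis screen; `NULL`
#'   means use the current simulation temperature.
#' @return Object of class `move_schedule`.
#' @export
move_schedule <- function(p_torsion = 0.60, p_trimer = 0.30,
                          p_pentamer = 0.075, p_nonamer = 0.025,
                          small_frac = 0.5, torsion_mag = 30,
                          trans_mag = 1, rot_mag = 10, t_rama = NULL) {
  p <- c(p_torsion, p_trimer, p_pentamer, p_nonamer)
  if (abs(sum(p) - 1) > 1e-9) stop("move probabilities must sum to 1")
  if (any(p < 0) || torsion_mag <= 0 || trans_mag <= 0 || rot_mag <= 0) {
    stop("probabilities must be non-negative and magnitudes positive")
  }
  structure(list(p_torsion = p_torsion, p_trimer = p_trimer,
                 p_pentamer = p_pentamer, p_nonamer = p_nonamer,
                 small_frac = small_frac, torsion_mag = torsion_mag,
                 trans_mag = trans_mag, rot_mag = rot_mag, t_rama = t_rama),
            class = "move_schedule")
}

# move-kind probabilities for a given peptide length, renormalized after
# excluding fragment kinds longer than the peptide
schedule_probs <- function(schedule, peptide_len) {
  p <- c(small = schedule$p_torsion * schedule$small_frac,
         shear = schedule$p_torsion * (1 - schedule$small_frac),
         trimer = schedule$p_trimer, pentamer = schedule$p_pentamer,
         nonamer = schedule$p_nonamer)
  if (peptide_len < 3) p["trimer"] <- 0
  if (peptide_len < 5) p["pentamer"] <- 0
  if (peptide_len < 9) p["nonamer"] <- 0
  p / sum(p)
}

#' Draw backbone move kinds
#'
#' Kinds whose fragment length exceeds the peptide length are excluded and
#' their probability mass redistributed proportionally over the rest.
#'
#' @param schedule A `move_schedule`.
#' @param peptide_len Peptide length (>= 3).
#' @param n Number of draws.
#' @return Character vector of kinds in
#'   `c("small", "shear", "trimer", "pentamer", "nonamer")`.
#' @export
choose_backbone_move <- function(schedule, peptide_len, n = 1) {
  if (peptide_len < 3) stop("peptide must have at least 3 residues")
  p <- schedule_probs(schedule, peptide_len)
  sample(names(p), size = n, replace = TRUE, prob = p)
}

#' Metropolis acceptance rule
#'
#' @param delta_e Energy change of the proposal.
#' @param T Temperature (> 0, arbitrary units).
#' @return Logical: accept the proposal.
#' @export
metropolis <- function(delta_e, T) {
  if (T <= 0) stop("Metropolis temperature must be positive")
  delta_e <= 0 || runif(1) < exp(-delta_e / T)
}

# Ramachandran Metropolis screen shared by small/shear moves
rama_screen <- function(chain, residues, tor_new, T, weights,
                        table = rama_table()) {
  cls <- c("generic", "glycine", "proline")
  d <- 0
  for (r in residues) {
    if (!(chain$defined[r, "phi"] && chain$defined[r, "psi"])) next
    lv_old <- rama_energy(chain$tor[r, 1], chain$tor[r, 2],
                          cls[chain$rama_class[r] + 1], table)
    lv_new <- rama_energy(tor_new[r, 1], tor_new[r, 2],
                          cls[chain$rama_class[r] + 1], table)
    d <- d + weights$w_rama * (lv_new - lv_old)
  }
  metropolis(d, T)
}

#' Small backbone move
#'
#' Perturbs one random residue's phi and psi by uniform(-m, m) with
#' m = `torsion_mag * T / 2`, screened by a Ramachandran Metropolis
#' criterion so that moves into non-favorable bins are discriminated
#' against. A screened-out proposal returns the input chain unchanged with
#' `rejected = TRUE` (it still counts as an executed move).
#'
#' @param chain A `pep_chain`.
#' @param schedule A `move_schedule`.
#' @param T Current temperature.
#' @param weights A `score_weights` (for the rama screen magnitude).
#' @return List with elements `chain`, `rejected`, `residue`.
#' @export
small_move <- function(chain, schedule, T, weights = score_weights()) {
  n <- chain_length(chain)
  res <- sample.int(n, 1)
  m <- schedule$torsion_mag * T / 2
  tor <- chain$tor
  tor[res, 1] <- tor[res, 1] + runif(1, -m, m)
  tor[res, 2] <- tor[res, 2] + runif(1, -m, m)
  t_rama <- if (is.null(schedule$t_rama)) T else schedule$t_rama
  if (!rama_screen(chain, res, tor, t_rama, weights)) {
    return(list(chain = chain, rejected = TRUE, residue = res))
  }
  list(chain = set_torsions(chain, tor), rejected = FALSE, residue = res)
}

#' Shear backbone move
#'
#' Draws one delta and applies psi(i-1) += delta, phi(i) -= delta, reducing
#' the downstream lever-arm motion relative to a small move; both affected
#' residues pass through the Ramachandran screen.
#'
#' @inheritParams small_move
#' @return List with elements `chain`, `rejected`, `residue` (the index i).
#' @export
shear_move <- function(chain, schedule, T, weights = score_weights()) {
  n <- chain_length(chain)
  if (n < 2) stop("shear move needs at least 2 residues")
  res <- 1 + sample.int(n - 1, 1)
  m <- schedule$torsion_mag * T / 2
  d <- runif(1, -m, m)
  tor <- chain$tor
  tor[res - 1, 2] <- tor[res - 1, 2] + d
  tor[res, 1] <- tor[res, 1] - d
  t_rama <- if (is.null(schedule$t_rama)) T else schedule$t_rama
  if (!rama_screen(chain, c(res - 1, res), tor, t_rama, weights)) {
    return(list(chain = chain, rejected = TRUE, residue = res))
  }
  list(chain = set_torsions(chain, tor), rejected = FALSE, residue = res)
}

# direction uniform on the unit sphere
random_unit_vector <- function() {
  repeat {
    u <- runif(2, -1, 1)
    s <- sum(u^2)
    if (s > 0 && s < 1) break
  }
  f <- 2 * sqrt(1 - s)
  c(u[1] * f, u[2] * f, 1 - 2 * s)
}

#' Rigid-body perturbation move
#'
#' Translation along a uniformly random direction with half-normal
#' magnitude of mean `trans_mag` (1 Angstrom by default) and rotation about
#' a uniformly random axis by a half-normal angle of mean `rot_mag` (10
#' degrees). The rotation pivot is `center` (default: the transform's
#' translation point; the simulation driver passes the peptide centroid).
#' Peptide internal torsions are untouched.
#'
#' @param xform A `rigid_xform`.
#' @param schedule A `move_schedule`.
#' @param center Optional xyz pivot for the rotation.
#' @return The proposed `rigid_xform`.
#' @export
rigid_body_move <- function(xform, schedule = move_schedule(),
                            center = NULL) {
  if (is.null(center)) center <- xform$t
  dt <- random_unit_vector() *
    abs(rnorm(1, 0, schedule$trans_mag * sqrt(pi / 2)))
  ang <- abs(rnorm(1, 0, schedule$rot_mag * sqrt(pi / 2)))
  rot <- rot_axis_angle(random_unit_vector(), ang)
  Rn <- reorthonormalize(rot %*% xform$R)
  tn <- as.numeric(rot %*% (xform$t - center)) + center + dt
  rigid_xform(Rn, tn)
}

#' Random starting-pose perturbation
#'
#' Gaussian rigid-body perturbation used to generate alternative starting
#' orientations: per-component translation with overall scale
#' `trans_sigma` (RMS magnitude, default 3 Angstrom) and rotation about a
#' random axis by a half-normal angle of scale `rot_sigma` (default 30
#' degrees; interpreted as the Gaussian standard deviation).
#'
#' @param xform A `rigid_xform`.
#' @param trans_sigma Translation scale in Angstrom.
#' @param rot_sigma Rotation scale in degrees.
#' @param center Optional rotation pivot (default: transform translation).
#' @return The perturbed `rigid_xform`.
#' @export
random_start_perturbation <- function(xform, trans_sigma = 3,
                                      rot_sigma = 30, center = NULL) {
  if (is.null(center)) center <- xform$t
  dt <- rnorm(3, 0, trans_sigma / sqrt(3))
  ang <- abs(rnorm(1, 0, rot_sigma))
  rot <- if (rot_sigma > 0) rot_axis_angle(random_unit_vector(), ang) else diag(3)
  Rn <- reorthonormalize(rot %*% xform$R)
  tn <- as.numeric(rot %*% (xform$t - center)) + center + dt
  rigid_xform(Rn, tn)
}
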