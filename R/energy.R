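# Coarse-grained surrogate energy: soft-sphere repulsion + short-range
# attraction over unified side-chain spheres, a coarse Ramachandran term,
# and the total / interface / peptide partitions used for model selection.

#' Score weights and ramp factors
#'
#' @param w_rep,w_att,w_rama Non-negative term weights (arbitrary energy
#'   units) for the repulsive, attractive and Ramachandran terms.
#' @param f_rep_start,f_att_start Starting ramp factors for refinement: the
#'   repulsive weight starts damped and the attractive weight inflated, and
#'   both are ramped linearly back to exactly 1 at the final ramp step.
#' @param a_total,a_interface,a_peptide Reweighted-score coefficients.
#' @return Object of class `score_weights`.
#' @export
score_weights <- function(w_rep = 1000, w_att = 1, w_rama = 1,
                          f_rep_start = 0.1, f_att_start = 2.0,
                          a_total = 1, a_interface = 1, a_peptide = 1) {
  if (any(c(w_rep, w_att, w_rama) < 0)) stop("weights must be non-negative")
  structure(list(w_rep = w_rep, w_att = w_att, w_rama = w_rama,
                 f_rep_start = f_rep_start, f_att_start = f_att_start,
                 a_total = a_total, a_interface = a_interface,
                 a_peptide = a_peptide),
            class = "score_weights")
}

weights_vec <- function(weights, f_rep = 1, f_att = 1) {
  c(weights$w_rep, weights$w_att, weights$w_rama, f_rep, f_att)
}

#' Pairwise sphere-sphere energy
#'
#' Soft-sphere repulsion inside contact and a parabolic attractive well
#' centred on the contact distance:
#' \deqn{rep = w_{rep} ((r_0 - d)/r_0)^2 \textrm{ for } d < r_0}
#' \deqn{att = -w_{att} (1 - ((d - r_0)/2)^2) \textrm{ for } |d - r_0| < 2}
#' The well is symmetric about \eqn{d = r_0} and fades to zero at both
#' rims, so the pair energy is continuous everywhere and over-penetration
#' loses attraction in addition to paying repulsion.
#'
#' @param d Distance(s) in Angstrom (vectorized).
#' @param r0 Contact distance: sum of the two sphere radii.
#' @param weights A `score_weights`.
#' @return List with numeric vectors `rep` and `att`.
#' @export
pair_energy <- function(d, r0, weights = score_weights()) {
  rep_ <- ifelse(d < r0, weights$w_rep * ((r0 - d) / r0)^2, 0)
  u <- (d - r0) / 2
  att <- ifelse(abs(u) < 1, -weights$w_att * (1 - u^2), 0)
  list(rep = rep_, att = att)
}

#' Ramachandran bin energy level
#'
#' @param phi,psi Backbone torsions in degrees (any wrap).
#' @param residue_class One of `"generic"`, `"glycine"`, `"proline"`.
#' @param table Level table from [rama_table()].
#' @return The bin level (favored 0, allowed 1, disallowed 3).
#' @export
rama_energy <- function(phi, psi, residue_class = "generic",
                        table = rama_table()) {
  m <- table[[match.arg(residue_class, names(table))]]
  m[cbind(rama_bin_index(wrap_angle(phi)), rama_bin_index(wrap_angle(psi)))]
}

#' Linear van-der-Waals weight ramp
#'
#' Interpolates the repulsive ramp factor from `f_rep_start` up to 1 and the
#' attractive factor from `f_att_start` down to 1; at step `n_steps - 1`
#' both are exactly 1.
#'
#' @param step 0-based ramp step, `0 <= step < n_steps`.
#' @param n_steps Total ramp steps.
#' @param weights A `score_weights`.
#' @return Named numeric vector `c(f_rep, f_att)`.
#' @export
ramp_weights <- function(step, n_steps, weights = score_weights()) {
  if (step < 0 || step >= n_steps) stop("ramp step out of range")
  frac <- if (n_steps == 1) 1 else step / (n_steps - 1)
  c(f_rep = weights$f_rep_start + (1 - weights$f_rep_start) * frac,
    f_att = weights$f_att_start + (1 - weights$f_att_start) * frac)
}

#' Reweighted selection score
#'
#' Weighted sum of the total, interface and peptide energy partitions used
#' to rank decoys and cluster representatives.
#'
#' @param breakdown A `score_breakdown`.
#' @param a_total,a_interface,a_peptide Coefficients.
#' @return Numeric score (lower is better).
#' @export
reweighted_score <- function(breakdown, a_total = 1, a_interface = 1,
                             a_peptide = 1) {
  a_total * breakdown$e_total + a_interface * breakdown$e_interface +
    a_peptide * breakdown$e_peptide
}

# assemble the system description consumed by the C++ core
build_sys <- function(pose, rama_tab = rama_table_flat()) {
  pep <- pose$peptide
  n <- chain_length(pep)
  pep_rad <- rep(BACKBONE_RADIUS, 5 * n)
  pep_rad[atom_is_cen(n)] <- pep$cen_rad
  mask <- pep$defined[, "phi"] & pep$defined[, "psi"]
  list(rec_xyz = pose$receptor$coords,
       rec_rad = pose$receptor$radii,
       rec_is_cen = as.integer(pose$receptor$is_cen),
       pep_rad = pep_rad,
       pep_res = as.integer(atom_residue_index(n) - 1L),
       pep_is_cen = as.integer(atom_is_cen(n)),
       cen_dist = pep$cen_dist,
       rama_class = as.integer(pep$rama_class),
       rama_mask = as.integer(mask),
       rama_tab = rama_tab,
       geom = as.numeric(ideal_geometry()),
       anchor = as.integer(if (is.null(pep$anchor)) 0L else pep$anchor - 1L))
}

#' Score a complex pose
#'
#' Sums the pairwise sphere energy over all CEN-CEN and CEN-backbone pairs
#' (intra-peptide pairs at sequence separation >= 3 and all peptide-receptor
#' pairs; receptor-internal pairs are constant and excluded) plus the
#' Ramachandran term over peptide residues with defined phi and psi, and
#' fills the total / interface / peptide partitions and the reweighted
#' selection score.
#'
#' @param pose A `complex_pose` with current coordinates.
#' @param weights A `score_weights`.
#' @param f_rep,f_att Ramp factors applied to the vdW weights (default 1).
#' @return Object of class `score_breakdown`: named list with `e_rep`,
#'   `e_att`, `e_rama`, `e_total`, `e_interface`, `e_peptide`, `reweighted`.
#' @export
score_pose <- function(pose, weights = score_weights(), f_rep = 1,
                       f_att = 1) {
  if (isTRUE(pose$peptide$stale)) {
    stop("peptide coordinates are stale; rebuild before scoring")
  }
  sys <- build_sys(pose)
  v <- cpp_score_xyz(sys, peptide_world_coords(pose),
                     tor_filled(pose$peptide),
                     weights_vec(weights, f_rep, f_att))
  b <- as.list(v)
  b$reweighted <- reweighted_score(b, weights$a_total, weights$a_interface,
                                   weights$a_peptide)
  structure(b, class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf(
    "score: total %.3f (rep %.3f att %.3f rama %.3f) interface %.3f peptide %.3f reweighted %.3f\n",
    x$e_total, x$e_rep, x$e_att, x$e_rama, x$e_interface, x$e_peptide,
    x$reweighted))
  invisible(x)
}

#' Write a decoy score table
#'
#' One row per decoy, tab-separated: decoy id, per-term energies, the
#' partitions and the reweighted selection score.
#'
#' @param scores Data frame as produced by [generate_decoys()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_score_table <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a decoy score table written by [write_score_table()]
#' @param path File path.
#' @return Data frame.
#' @export
read_score_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
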