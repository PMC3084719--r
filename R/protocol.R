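# Staged simulation driver: prepack, stage Ia low-resolution fold-and-dock
# under simulated annealing, stage Ib Monte-Carlo-with-minimization
# refinement, and the multi-decoy generation loop.

#' Protocol configuration
#'
#' @param n_outer Outer fold-and-dock cycles (default 10).
#' @param t_start,t_end Metropolis temperature annealed geometrically from
#'   2.0 in the first outer cycle to 0.6 in the last.
#' @param n_rigid_moves,n_backbone_moves Proposals per inner simulation
#'   (both 50); rejected Ramachandran-screened proposals count as executed
#'   moves.
#' @param n_refine Refinement (MCM) cycles with van-der-Waals weight
#'   ramping (default 8).
#' @param n_refine_moves Proposals per refinement cycle.
#' @param refine_scale Magnitude factor for refinement perturbations
#'   relative to the stage-Ia schedule (default 0.25).
#' @param nstruct Number of independent decoys to generate.
#' @param seed Master seed; per-run seeds are `seed + run_index`.
#' @param schedule A [move_schedule()].
#' @param weights A [score_weights()].
#' @param select_top_n,cluster_radius Selection parameters forwarded to the
#'   clustering step.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(n_outer = 10, t_start = 2.0, t_end = 0.6,
                            n_rigid_moves = 50, n_backbone_moves = 50,
                            n_refine = 8, n_refine_moves = 6,
                            refine_scale = 0.25, nstruct = 100, seed = 1,
                            schedule = move_schedule(),
                            weights = score_weights(),
                            select_top_n = 500, cluster_radius = 2.0) {
  stopifnot(n_outer >= 1, t_start > t_end, t_end > 0, n_rigid_moves >= 1,
            n_backbone_moves >= 1, n_refine >= 1, n_refine_moves >= 1)
  structure(list(n_outer = n_outer, t_start = t_start, t_end = t_end,
                 n_rigid_moves = n_rigid_moves,
                 n_backbone_moves = n_backbone_moves, n_refine = n_refine,
                 n_refine_moves = n_refine_moves,
                 refine_scale = refine_scale, nstruct = nstruct,
                 seed = seed, schedule = schedule, weights = weights,
                 select_top_n = select_top_n,
                 cluster_radius = cluster_radius),
            class = "protocol_config")
}

#' Annealing temperature of an outer cycle
#'
#' Geometric interpolation from `t_start` (cycle 1) to `t_end` (cycle
#' `n_outer`).
#'
#' @param cycle 1-based outer-cycle index.
#' @param config A `protocol_config`.
#' @return Temperature (arbitrary units).
#' @export
anneal_temperature <- function(cycle, config) {
  if (cycle < 1 || cycle > config$n_outer) stop("cycle out of range")
  if (config$n_outer == 1) return(config$t_start)
  config$t_start * (config$t_end / config$t_start)^((cycle - 1) /
                                                      (config$n_outer - 1))
}

#' Prepack: relieve internal side-chain clashes
#'
#' Greedy local adjustment of the peptide side-chain centroid distances
#' along the CA-CEN axis in 0.5 Angstrom steps, accepted only when the
#' repulsive energy strictly decreases. The receptor and the peptide
#' backbone are untouched; the operation is idempotent on clash-free poses.
#'
#' @param pose A `complex_pose`.
#' @param weights A `score_weights`.
#' @return The prepacked pose.
#' @export
prepack <- function(pose, weights = score_weights()) {
  n <- chain_length(pose$peptide)
  sys <- build_sys(pose)
  wvec <- weights_vec(weights)
  tor <- tor_filled(pose$peptide)
  world <- peptide_world_coords(pose)
  cen_rows <- which(atom_is_cen(n))
  ca_rows <- cen_rows - 3L
  dirs <- (world[cen_rows, , drop = FALSE] - world[ca_rows, , drop = FALSE]) /
    pose$peptide$cen_dist
  dist <- pose$peptide$cen_dist
  e_rep_of <- function(w) cpp_score_xyz(sys, w, tor, wvec)[["e_rep"]]
  current <- e_rep_of(world)
  for (sweep in 1:10) {
    improved <- FALSE
    for (r in seq_len(n)) {
      for (step in c(-0.5, 0.5, -0.25, 0.25, -0.1, 0.1)) {
        d_new <- dist[r] + step
        if (d_new < 0.05 || d_new > 4.5) next
        trial <- world
        trial[cen_rows[r], ] <- world[ca_rows[r], ] + d_new * dirs[r, ]
        e_new <- e_rep_of(trial)
        if (e_new < current - 1e-12) {
          world <- trial
          dist[r] <- d_new
          current <- e_new
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  pose$peptide$cen_dist <- dist
  pose$peptide <- rebuild_chain(pose$peptide)
  pose
}

pose_from_state <- function(pose, st, use_best = FALSE) {
  tor <- if (use_best) st$best_torsions else st$torsions
  Rm <- if (use_best) st$best_R else st$R
  tv <- if (use_best) st$best_t else st$t
  colnames(tor) <- c("phi", "psi", "omega")
  pose$peptide <- set_torsions(pose$peptide, tor)
  pose$xform <- rigid_xform(reorthonormalize(Rm), tv)
  pose
}

#' Rigid-body inner Monte-Carlo simulation
#'
#' 50 random rigid-body transformations (1 Angstrom / 10 degree mean
#' magnitudes), each accepted or rejected by the Metropolis criterion on
#' the total energy. Peptide torsions are untouched.
#'
#' @param pose Current pose.
#' @param T Metropolis temperature.
#' @param config A `protocol_config`.
#' @param f_rep,f_att Optional vdW ramp factors.
#' @param log_moves Keep the per-proposal move log.
#' @return List: `pose` (final), `best_pose`, `best_e`, `n_accept`, `log`.
#' @export
rigid_body_inner_sim <- function(pose, T, config, f_rep = 1, f_att = 1,
                                 log_moves = TRUE) {
  sys <- build_sys(pose)
  st <- cpp_rigid_inner(sys, tor_filled(pose$peptide), pose$xform$R,
                        pose$xform$t,
                        weights_vec(config$weights, f_rep, f_att), T,
                        config$n_rigid_moves, config$schedule$trans_mag,
                        config$schedule$rot_mag, log_moves)
  list(pose = pose_from_state(pose, st),
       best_pose = pose_from_state(pose, st, use_best = TRUE),
       best_e = st$best_e, e_total = st$e_total, n_accept = st$n_accept,
       log = as.data.frame(st$log))
}

#' Backbone inner Monte-Carlo simulation
#'
#' 50 random backbone moves (small / shear / fragment insertion as drawn by
#' the move schedule), Metropolis-evaluated on the total energy while the
#' rigid-body orientation stays fixed.
#'
#' @inheritParams rigid_body_inner_sim
#' @param frags A `fragment_library`.
#' @return As [rigid_body_inner_sim()].
#' @export
backbone_inner_sim <- function(pose, T, config, frags, f_rep = 1,
                               f_att = 1, log_moves = TRUE) {
  sys <- build_sys(pose)
  n <- chain_length(pose$peptide)
  # raw kind probabilities; the sampler renormalizes after excluding
  # fragment kinds that do not fit the peptide or have no fragments
  probs <- c(config$schedule$p_torsion * config$schedule$small_frac,
             config$schedule$p_torsion * (1 - config$schedule$small_frac),
             config$schedule$p_trimer, config$schedule$p_pentamer,
             config$schedule$p_nonamer)
  t_rama <- if (is.null(config$schedule$t_rama)) T else config$schedule$t_rama
  st <- cpp_backbone_inner(sys, tor_filled(pose$peptide), pose$xform$R,
                           pose$xform$t,
                           weights_vec(config$weights, f_rep, f_att), T,
                           config$n_backbone_moves, probs,
                           config$schedule$torsion_mag * T / 2, t_rama,
                           frag_matrix(frags, 3), frag_matrix(frags, 5),
                           frag_matrix(frags, 9), log_moves)
  out <- pose_from_state(pose, st)
  out$xform <- pose$xform  # backbone moves never touch the transform
  list(pose = out,
       best_pose = pose_from_state(pose, st, use_best = TRUE),
       best_e = st$best_e, e_total = st$e_total, n_accept = st$n_accept,
       log = as.data.frame(st$log))
}

#' Stage Ia: low-resolution ab initio fold-and-dock
#'
#' Alternates the rigid-body and backbone inner simulations for `n_outer`
#' cycles under the geometric annealing schedule, and tracks the
#' best-energy pose visited, which is what the downstream refinement uses.
#'
#' @param start_pose Prepacked starting pose.
#' @param config A `protocol_config`.
#' @param frags A `fragment_library`.
#' @param log_moves Keep per-proposal logs.
#' @return List: `pose` (best-energy visited), `final_pose`, `best_e`,
#'   `log` (per-proposal rows), `cycles` (per-cycle summary).
#' @export
lowres_abinitio <- function(start_pose, config, frags, log_moves = FALSE) {
  # drive the compiled inner simulations on raw state (torsions +
  # transform); poses are materialized only at the end
  sys <- build_sys(start_pose)
  sch <- config$schedule
  probs <- c(sch$p_torsion * sch$small_frac,
             sch$p_torsion * (1 - sch$small_frac),
             sch$p_trimer, sch$p_pentamer, sch$p_nonamer)
  f3 <- frag_matrix(frags, 3); f5 <- frag_matrix(frags, 5)
  f9 <- frag_matrix(frags, 9)
  wvec <- weights_vec(config$weights)
  tor <- tor_filled(start_pose$peptide)
  Rm <- start_pose$xform$R
  tv <- start_pose$xform$t
  best <- list(tor = tor, R = Rm, t = tv,
               e = score_pose(start_pose, config$weights)$e_total)
  logs <- list()
  cycles <- NULL
  for (cycle in seq_len(config$n_outer)) {
    T <- anneal_temperature(cycle, config)
    rb <- cpp_rigid_inner(sys, tor, Rm, tv, wvec, T, config$n_rigid_moves,
                          sch$trans_mag, sch$rot_mag, log_moves)
    tor <- rb$torsions; Rm <- rb$R; tv <- rb$t
    if (rb$best_e < best$e) {
      best <- list(tor = rb$best_torsions, R = rb$best_R, t = rb$best_t,
                   e = rb$best_e)
    }
    t_rama <- if (is.null(sch$t_rama)) T else sch$t_rama
    bb <- cpp_backbone_inner(sys, tor, Rm, tv, wvec, T,
                             config$n_backbone_moves, probs,
                             sch$torsion_mag * T / 2, t_rama, f3, f5, f9,
                             log_moves)
    tor <- bb$torsions; Rm <- bb$R; tv <- bb$t
    if (bb$best_e < best$e) {
      best <- list(tor = bb$best_torsions, R = bb$best_R, t = bb$best_t,
                   e = bb$best_e)
    }
    if (log_moves) {
      logs[[cycle]] <- cbind(rbind(as.data.frame(rb$log),
                                   as.data.frame(bb$log)), cycle = cycle)
    }
    cycles <- rbind(cycles, data.frame(
      cycle = cycle, temp = T, rigid_accept = rb$n_accept,
      backbone_accept = bb$n_accept, e_total = bb$e_total))
  }
  mk_pose <- function(st) {
    p <- start_pose
    colnames(st$tor) <- c("phi", "psi", "omega")
    p$peptide <- set_torsions(p$peptide, st$tor)
    p$xform <- rigid_xform(reorthonormalize(st$R), st$t)
    p
  }
  list(pose = mk_pose(best),
       final_pose = mk_pose(list(tor = tor, R = Rm, t = tv)),
       best_e = best$e,
       log = if (log_moves) do.call(rbind, logs) else NULL, cycles = cycles)
}

#' Stage Ib: Monte-Carlo-with-minimization refinement
#'
#' `n_refine` cycles at fixed temperature `t_end`. Each cycle ramps the
#' repulsive vdW weight up from `f_rep_start` and the attractive weight
#' down from `f_att_start` (both exactly 1 in the final cycle), and runs
#' small-magnitude rigid-body and small/shear proposals (fragment
#' insertions disabled; magnitudes scaled by `refine_scale`), each followed
#' by coordinate-descent minimization over the perturbed degrees of freedom
#' before the Metropolis decision.
#'
#' @param pose Coarse model from stage Ia.
#' @param config A `protocol_config`.
#' @param log_moves Keep per-proposal logs.
#' @return List: `pose` (final refined), `log`, `cycles`.
#' @export
refine <- function(pose, config, log_moves = FALSE) {
  logs <- list()
  cycles <- NULL
  sch <- config$schedule
  sys <- build_sys(pose)
  tor <- tor_filled(pose$peptide)
  Rm <- pose$xform$R
  tv <- pose$xform$t
  for (cycle in seq_len(config$n_refine)) {
    f <- ramp_weights(cycle - 1, config$n_refine, config$weights)
    st <- cpp_refine_cycle(sys, tor, Rm, tv,
                           weights_vec(config$weights, f["f_rep"],
                                       f["f_att"]),
                           config$t_end, config$n_refine_moves,
                           sch$trans_mag * config$refine_scale,
                           sch$rot_mag * config$refine_scale,
                           sch$torsion_mag * config$t_end / 2 *
                             config$refine_scale,
                           1e-3, log_moves)
    tor <- st$torsions; Rm <- st$R; tv <- st$t
    if (log_moves) logs[[cycle]] <- cbind(as.data.frame(st$log),
                                          cycle = cycle)
    cycles <- rbind(cycles, data.frame(
      cycle = cycle, f_rep = unname(f["f_rep"]), f_att = unname(f["f_att"]),
      n_accept = st$n_accept, e_total = st$e_total))
  }
  colnames(tor) <- c("phi", "psi", "omega")
  pose$peptide <- set_torsions(pose$peptide, tor)
  pose$xform <- rigid_xform(reorthonormalize(Rm), tv)
  list(pose = pose, log = if (log_moves) do.call(rbind, logs) else NULL,
       cycles = cycles)
}

#' Generate an ensemble of decoys
#'
#' Runs the full two-stage protocol `nstruct` times from the (prepacked)
#' start, with per-run seeds derived from the master seed, and scores every
#' final model. Failed runs are recorded and skipped.
#'
#' @param start_pose Starting pose (extended peptide at the binding site).
#' @param config A `protocol_config`.
#' @param frags A `fragment_library`.
#' @param native Optional native `complex_pose`; when given, interface
#'   backbone RMSDs are added to the score table.
#' @param out_dir Optional directory: writes `score.sc` and decoy PDBs.
#' @return Object of class `decoy_set`: list with `decoys` (list of decoy
#'   records), `scores` (data frame), `config`, `start_pose`.
#' @export
generate_decoys <- function(start_pose, config, frags, native = NULL,
                            out_dir = NULL) {
  if (config$nstruct == 0) {
    warning("nstruct = 0: no decoys generated")
    return(structure(list(decoys = list(), scores = NULL, config = config,
                          start_pose = start_pose), class = "decoy_set"))
  }
  start_pose <- prepack(start_pose, config$weights)
  decoys <- list()
  rows <- list()
  failures <- 0L
  # per-run seeds drawn from a master-seeded stream, so different master
  # seeds give fully independent run-seed sets
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, config$nstruct)
  for (run in seq_len(config$nstruct)) {
    run_seed <- run_seeds[run]
    rec <- tryCatch({
      set.seed(run_seed)
      lo <- lowres_abinitio(start_pose, config, frags)
      rf <- refine(lo$pose, config)
      bd <- score_pose(rf$pose, config$weights)
      id <- sprintf("decoy_%04d", run)
      list(id = id, pose = rf$pose, breakdown = bd, seed = run_seed,
           lowres_accepts = sum(lo$cycles$rigid_accept +
                                  lo$cycles$backbone_accept),
           refine_accepts = sum(rf$cycles$n_accept))
    }, error = function(e) {
      warning("run ", run, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) { failures <- failures + 1L; next }
    row <- data.frame(
      decoy = rec$id, e_rep = rec$breakdown$e_rep,
      e_att = rec$breakdown$e_att, e_rama = rec$breakdown$e_rama,
      e_total = rec$breakdown$e_total,
      e_interface = rec$breakdown$e_interface,
      e_peptide = rec$breakdown$e_peptide,
      reweighted = rec$breakdown$reweighted, seed = rec$seed,
      stringsAsFactors = FALSE)
    if (!is.null(native)) {
      row$irmsd <- peptide_backbone_rmsd(rec$pose, native,
                                         interface_only = TRUE)
      row$rmsd <- peptide_backbone_rmsd(rec$pose, native,
                                        interface_only = FALSE)
    }
    rows[[rec$id]] <- row
    decoys[[rec$id]] <- rec
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  out <- structure(list(decoys = decoys, scores = scores, config = config,
                        start_pose = start_pose, failures = failures),
                   class = "decoy_set")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_score_table(scores, file.path(out_dir, "score.sc"))
    for (rec in decoys) {
      write_pdb(rec$pose, file.path(out_dir, paste0(rec$id, ".pdb")))
    }
  }
  out
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("decoy_set:", length(x$decoys), "decoys")
  if (x$failures > 0) cat(" (", x$failures, "failed runs )")
  cat("\n")
  if (!is.null(x$scores)) {
    cat("  e_total range:",
        sprintf("%.2f .. %.2f", min(x$scores$e_total),
                max(x$scores$e_total)), "\n")
  }
  invisible(x)
}
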