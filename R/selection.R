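# Decoy selection and evaluation: RMSD metrics, top-500 filtering, greedy
# RMSD clustering, cluster ranking and success classification.

pose_backbone_rows <- function(n, residues = seq_len(n)) {
  as.vector(vapply(residues, function(r) as.integer(5 * (r - 1)) + 1:4, integer(4)))
}

# receptor backbone superposition transform (model -> reference frame)
receptor_superposition <- function(model, reference) {
  keep <- !model$receptor$is_cen
  kabsch(model$receptor$coords[keep, , drop = FALSE],
         reference$receptor$coords[!reference$receptor$is_cen, ,
                                   drop = FALSE])
}

#' Interface residues of a native complex
#'
#' Peptide residues with any represented atom (backbone or centroid)
#' within `cutoff` of any receptor atom.
#'
#' @param native A `complex_pose`.
#' @param cutoff Distance cutoff in Angstrom (default 4).
#' @return Integer vector of 1-based peptide residue indices.
#' @export
interface_residues <- function(native, cutoff = 4.0) {
  pw <- peptide_world_coords(native)
  rc <- native$receptor$coords
  n <- chain_length(native$peptide)
  res <- atom_residue_index(n)
  hit <- logical(n)
  for (r in seq_len(n)) {
    sub <- pw[res == r, , drop = FALSE]
    d2 <- outer(rowSums(sub^2), rowSums(rc^2), "+") - 2 * sub %*% t(rc)
    if (min(d2) <= cutoff^2) hit[r] <- TRUE
  }
  which(hit)
}

#' Peptide backbone RMSD after receptor superposition
#'
#' The model receptor backbone is least-squares superposed onto the
#' reference receptor backbone; the RMSD is then computed over peptide
#' N, CA, C, O atoms without further fitting. With `interface_only` the
#' calculation is restricted to reference-native peptide residues within
#' 4 Angstrom of the receptor (the interface backbone RMSD, iRMSD).
#'
#' @param model,reference `complex_pose` objects with equal peptide lengths
#'   and residue-wise corresponding receptors.
#' @param interface_only Restrict to native interface residues.
#' @return RMSD in Angstrom.
#' @export
peptide_backbone_rmsd <- function(model, reference, interface_only = FALSE) {
  n <- chain_length(model$peptide)
  if (n != chain_length(reference$peptide)) {
    stop("peptide lengths differ between model and reference")
  }
  residues <- seq_len(n)
  if (interface_only) {
    residues <- interface_residues(reference)
    if (length(residues) == 0) {
      warning("empty interface set; falling back to all peptide residues")
      residues <- seq_len(n)
    }
  }
  xf <- receptor_superposition(model, reference)
  rows <- pose_backbone_rows(n, residues)
  A <- xform_apply(xf, peptide_world_coords(model))[rows, , drop = FALSE]
  B <- peptide_world_coords(reference)[rows, , drop = FALSE]
  rmsd_xyz(A, B)
}

#' Torsion-space RMSD between two peptide chains
#'
#' Root-mean-square of the wrapped angular difference over phi/psi pairs
#' defined in both chains.
#'
#' @param chain_a,chain_b `pep_chain` objects of equal length.
#' @return RMSD in degrees.
#' @export
torsion_space_rmsd <- function(chain_a, chain_b) {
  if (chain_length(chain_a) != chain_length(chain_b)) {
    stop("chain lengths differ")
  }
  keep <- chain_a$defined[, 1:2] & chain_b$defined[, 1:2]
  d <- wrap_angle(chain_a$tor[, 1:2] - chain_b$tor[, 1:2])[keep]
  if (length(d) == 0) return(0)
  sqrt(mean(d^2))
}

#' Best contiguous k-mer all-atom RMSD
#'
#' After receptor superposition, the minimum over all contiguous k-residue
#' windows of the RMSD over all represented peptide atoms (backbone +
#' centroid) in the window, with no refitting.
#'
#' @param model,reference `complex_pose` objects.
#' @param k Window length (use 5 for peptides shorter than 6).
#' @return RMSD in Angstrom.
#' @export
best_subsegment_rmsd <- function(model, reference, k = 6) {
  n <- chain_length(model$peptide)
  if (k > n) stop("window length exceeds peptide length")
  xf <- receptor_superposition(model, reference)
  A <- xform_apply(xf, peptide_world_coords(model))
  B <- peptide_world_coords(reference)
  res <- atom_residue_index(n)
  best <- Inf
  for (s in seq_len(n - k + 1)) {
    rows <- which(res >= s & res <= s + k - 1)
    best <- min(best, rmsd_xyz(A[rows, , drop = FALSE],
                               B[rows, , drop = FALSE]))
  }
  best
}

#' Select the top-scoring decoys
#'
#' @param score_table Data frame with a `decoy` id column.
#' @param n Number of decoys to keep (default 500).
#' @param by Score column (default `"reweighted"`, lower is better).
#' @return The selected rows, ordered by score with decoy-id tie-breaks.
#' @export
select_top <- function(score_table, n = 500, by = "reweighted") {
  if (is.null(score_table) || nrow(score_table) == 0) {
    stop("empty score table")
  }
  if (!by %in% names(score_table)) stop("unknown score column: ", by)
  ord <- order(score_table[[by]], score_table$decoy)
  if (nrow(score_table) < n) {
    warning("only ", nrow(score_table), " decoys available (wanted ", n, ")")
  }
  score_table[ord[seq_len(min(n, nrow(score_table)))], , drop = FALSE]
}

# pairwise peptide backbone RMSD between decoys; all decoys share the same
# rigid receptor frame, so no superposition is needed
decoy_rmsd_matrix <- function(poses) {
  n_dec <- length(poses)
  n <- chain_length(poses[[1]]$peptide)
  rows <- pose_backbone_rows(n)
  mats <- lapply(poses, function(p) peptide_world_coords(p)[rows, ,
                                                           drop = FALSE])
  m <- matrix(0, n_dec, n_dec)
  for (i in seq_len(n_dec - 1)) {
    for (j in (i + 1):n_dec) {
      m[i, j] <- m[j, i] <- rmsd_xyz(mats[[i]], mats[[j]])
    }
  }
  m
}

#' Greedy RMSD clustering of decoys
#'
#' Greedy largest-neighborhood clustering: repeatedly take the unassigned
#' decoy with the most unassigned neighbors within `radius` (peptide
#' backbone RMSD over all residues, in the common receptor frame), form a
#' cluster from it and its neighbors, remove them and repeat. The cluster
#' representative is the member with the lowest reweighted score; all ties
#' are broken by decoy id.
#'
#' @param decoy_set A `decoy_set`, or a list with `decoys`/`scores`.
#' @param radius Cluster radius in Angstrom (default 2).
#' @param ids Optional subset of decoy ids to cluster (e.g. the top 500).
#' @return List of `decoy_cluster` objects (unranked).
#' @export
cluster_decoys <- function(decoy_set, radius = 2.0, ids = NULL) {
  scores <- decoy_set$scores
  if (is.null(ids)) ids <- scores$decoy
  ids <- sort(ids)
  if (length(ids) == 0) stop("no decoys to cluster")
  poses <- lapply(decoy_set$decoys[ids], function(d) d$pose)
  rew <- scores$reweighted[match(ids, scores$decoy)]
  m <- decoy_rmsd_matrix(poses)
  unassigned <- rep(TRUE, length(ids))
  clusters <- list()
  while (any(unassigned)) {
    # neighbor counts among unassigned decoys (self included)
    counts <- vapply(seq_along(ids), function(i) {
      if (!unassigned[i]) return(-1L)
      sum(m[i, unassigned] <= radius)
    }, 0L)
    center <- which.max(counts)  # ties: lowest index = smallest id
    members <- which(unassigned & m[center, ] <= radius)
    rep_i <- members[order(rew[members], ids[members])][1]
    clusters[[length(clusters) + 1]] <- structure(list(
      members = ids[members], center = ids[center],
      representative = ids[rep_i], rep_score = rew[rep_i], rank = NA_integer_),
      class = "decoy_cluster")
    unassigned[members] <- FALSE
  }
  clusters
}

#' Rank clusters by representative energy
#'
#' @param clusters List of `decoy_cluster` objects.
#' @return The clusters ordered and numbered by ascending representative
#'   reweighted score (ties by representative id).
#' @export
rank_clusters <- function(clusters) {
  ord <- order(vapply(clusters, function(cl) cl$rep_score, 0),
               vapply(clusters, function(cl) cl$representative, ""))
  out <- clusters[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' @export
print.decoy_cluster <- function(x, ...) {
  cat(sprintf("cluster rank %s: %d members, representative %s (%.3f)\n",
              ifelse(is.na(x$rank), "?", x$rank), length(x$members),
              x$representative, x$rep_score))
  invisible(x)
}

#' Classify a docking run against a native reference
#'
#' A model is near-native when its peptide interface backbone RMSD is at
#' most 2 Angstrom. Successful sampling means any generated decoy is
#' near-native; successful ranking means a near-native cluster
#' representative appears among the ten lowest-energy clusters.
#'
#' @param ranked_clusters Output of [rank_clusters()].
#' @param decoy_set The full `decoy_set`.
#' @param native Native `complex_pose`.
#' @param irmsd_cut Near-native threshold (default 2 Angstrom).
#' @return Object of class `success_report`: `sampled_near_native`,
#'   `rank_of_first_near_native` (NA if none), `best_irmsd`,
#'   `best_irmsd_top10`, `best_kmer_rmsd_top10`, `rep_irmsd`.
#' @export
classify_run <- function(ranked_clusters, decoy_set, native,
                         irmsd_cut = 2.0) {
  irmsd_of <- function(id) {
    peptide_backbone_rmsd(decoy_set$decoys[[id]]$pose, native,
                          interface_only = TRUE)
  }
  all_ids <- names(decoy_set$decoys)
  all_irmsd <- vapply(all_ids, irmsd_of, 0)
  rep_irmsd <- vapply(ranked_clusters, function(cl) irmsd_of(cl$representative), 0)
  top10 <- ranked_clusters[seq_len(min(10, length(ranked_clusters)))]
  top10_irmsd <- rep_irmsd[seq_len(length(top10))]
  k <- if (chain_length(native$peptide) < 6) 5 else 6
  top10_kmer <- vapply(top10, function(cl) {
    best_subsegment_rmsd(decoy_set$decoys[[cl$representative]]$pose, native,
                         k = k)
  }, 0)
  nn <- which(rep_irmsd <= irmsd_cut)
  structure(list(
    sampled_near_native = any(all_irmsd <= irmsd_cut),
    rank_of_first_near_native = if (length(nn) == 0) NA_integer_ else
      ranked_clusters[[nn[1]]]$rank,
    best_irmsd = min(all_irmsd),
    best_irmsd_top10 = min(top10_irmsd),
    best_kmer_rmsd_top10 = min(top10_kmer),
    rep_irmsd = rep_irmsd, kmer = k), class = "success_report")
}

#' @export
print.success_report <- function(x, ...) {
  cat(sprintf(
    "success_report: sampled near-native %s; first near-native rank %s\n",
    x$sampled_near_native,
    ifelse(is.na(x$rank_of_first_near_native), "none",
           x$rank_of_first_near_native)))
  cat(sprintf("  best iRMSD %.2f A; top-10 best iRMSD %.2f A; top-10 best %d-mer %.2f A\n",
              x$best_irmsd, x$best_irmsd_top10, x$kmer,
              x$best_kmer_rmsd_top10))
  invisible(x)
}

#' Energy-landscape (funnel) table
#'
#' One row per decoy with its interface backbone RMSD, selection score,
#' top-500 membership and cluster rank; the maximal energy among the
#' top-500 is attached as the `top500_threshold` attribute.
#'
#' @param decoy_set A `decoy_set`.
#' @param native Native `complex_pose`.
#' @param top_n Size of the selection set (default 500).
#' @param ranked_clusters Optional ranked clusters to annotate membership.
#' @return Data frame (`decoy`, `irmsd`, `reweighted`, `in_top500`,
#'   `cluster_rank`).
#' @export
landscape_table <- function(decoy_set, native, top_n = 500,
                            ranked_clusters = NULL) {
  scores <- decoy_set$scores
  irmsd <- vapply(scores$decoy, function(id) {
    peptide_backbone_rmsd(decoy_set$decoys[[id]]$pose, native,
                          interface_only = TRUE)
  }, 0)
  top <- suppressWarnings(select_top(scores, n = top_n))
  in_top <- scores$decoy %in% top$decoy
  rank <- rep(NA_integer_, nrow(scores))
  if (!is.null(ranked_clusters)) {
    for (cl in ranked_clusters) {
      rank[scores$decoy %in% cl$members] <- cl$rank
    }
  }
  out <- data.frame(decoy = scores$decoy, irmsd = irmsd,
                    reweighted = scores$reweighted, in_top500 = in_top,
                    cluster_rank = rank, stringsAsFactors = FALSE)
  attr(out, "top500_threshold") <- max(scores$reweighted[in_top])
  out
}

#' Run the full selection step on a decoy set
#'
#' Top-N filtering, clustering, ranking and (when a native is supplied)
#' success classification.
#'
#' @param decoy_set A `decoy_set`.
#' @param native Optional native `complex_pose`.
#' @param top_n,radius Selection parameters.
#' @return List: `clusters` (ranked), `report` (or NULL), `top` (selected
#'   score rows).
#' @export
select_models <- function(decoy_set, native = NULL, top_n = 500,
                          radius = 2.0) {
  top <- suppressWarnings(select_top(decoy_set$scores, n = top_n))
  clusters <- rank_clusters(cluster_decoys(decoy_set, radius = radius,
                                           ids = top$decoy))
  report <- if (!is.null(native)) {
    classify_run(clusters, decoy_set, native)
  }
  list(clusters = clusters, report = report, top = top)
}
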