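# construct a synthetic decoy set: copies of the native peptide displaced
# by known offsets, with prescribed selection scores
synthetic_decoys <- function(offsets, scores = NULL) {
  sys <- toy_fixture()
  ids <- sprintf("decoy_%04d", seq_along(offsets))
  decoys <- list()
  for (k in seq_along(offsets)) {
    pose <- sys$native
    pose$xform$t <- pose$xform$t + offsets[[k]]
    decoys[[ids[k]]] <- list(id = ids[k], pose = pose)
  }
  if (is.null(scores)) scores <- seq_along(offsets)
  structure(list(decoys = decoys,
                 scores = data.frame(decoy = ids, reweighted = scores,
                                     stringsAsFactors = FALSE)),
            class = "decoy_set")
}

test_that("backbone RMSD behaves under displacement and superposition", {
  sys <- toy_fixture()
  expect_equal(peptide_backbone_rmsd(sys$native, sys$native), 0)
  moved <- sys$native
  moved$xform$t <- moved$xform$t + c(1, 0, 0)
  expect_equal(peptide_backbone_rmsd(moved, sys$native), 1, tolerance = 1e-9)
  expect_equal(peptide_backbone_rmsd(moved, sys$native,
                                     interface_only = TRUE), 1,
               tolerance = 1e-9)
  # a whole-complex rotation is removed by receptor superposition
  rot <- rot_axis_angle(c(0, 0, 1), 90)
  spun <- sys$native
  spun$receptor$coords <- sys$native$receptor$coords %*% t(rot)
  spun$xform <- rigid_xform(
    pepdock:::reorthonormalize(rot %*% sys$native$xform$R),
    as.numeric(rot %*% sys$native$xform$t))
  expect_lt(peptide_backbone_rmsd(spun, sys$native), 1e-6)
  short <- sys$native
  short$peptide <- test_chain("AKL")
  expect_error(peptide_backbone_rmsd(short, sys$native), "lengths")
})

test_that("torsion-space RMSD wraps and is symmetric", {
  a <- test_chain("AKLAE", helix_torsions(5))
  expect_equal(torsion_space_rmsd(a, a), 0)
  tor <- a$tor
  tor[3, 1] <- 179
  b <- set_torsions(a, tor)
  tor[3, 1] <- -179
  c_ <- set_torsions(a, tor)
  # single pair differing by 2 degrees across the wrap; 8 defined pairs
  expect_equal(torsion_space_rmsd(b, c_), sqrt(2^2 / 8), tolerance = 1e-9)
  expect_equal(torsion_space_rmsd(b, c_), torsion_space_rmsd(c_, b))
})

test_that("best subsegment RMSD equals the window-enumeration oracle", {
  sys <- toy_fixture()
  model <- sys$native
  model$xform$t <- model$xform$t + c(0.8, 0, 0.4)
  expect_equal(best_subsegment_rmsd(sys$native, sys$native, k = 6), 0)
  got <- best_subsegment_rmsd(model, sys$native, k = 6)
  # oracle: direct enumeration over all hexamer windows
  A <- peptide_world_coords(model)
  B <- peptide_world_coords(sys$native)
  res <- pepdock:::atom_residue_index(8)
  oracle <- min(vapply(1:3, function(s) {
    rows <- which(res >= s & res <= s + 5)
    sqrt(mean(rowSums((A[rows, ] - B[rows, ])^2)))
  }, 0))
  expect_equal(got, oracle, tolerance = 1e-9)
  # the minimum never exceeds any specific window
  expect_lte(got, sqrt(mean(rowSums((A[res <= 6, ] - B[res <= 6, ])^2))))
  expect_error(best_subsegment_rmsd(sys$native, sys$native, k = 9), "exceeds")
})

test_that("top-N selection orders by score with id tie-breaks", {
  tab <- data.frame(decoy = sprintf("d%02d", 1:30),
                    reweighted = c(rep(1, 5), 31:55),
                    stringsAsFactors = FALSE)
  top <- select_top(tab, n = 10)
  expect_equal(nrow(top), 10)
  expect_equal(top$decoy[1:5], sprintf("d%02d", 1:5))
  expect_warning(all_rows <- select_top(tab, n = 100), "available")
  expect_equal(nrow(all_rows), 30)
  expect_error(select_top(tab, by = "nope"), "unknown")
  expect_error(select_top(tab[0, ], 5), "empty")
})

test_that("greedy clustering finds the planted bundle structure", {
  # two tight bundles >= 10 A apart plus one outlier
  offs <- c(lapply(c(0, 0.3, 0.5), function(d) c(d, 0, 0)),
            lapply(c(0, 0.4), function(d) c(12 + d, 0, 0)),
            list(c(40, 0, 0)))
  ds <- synthetic_decoys(offs, scores = c(5, 1, 3, 2, 4, 6))
  cl <- cluster_decoys(ds, radius = 2)
  expect_length(cl, 3)
  sizes <- sort(vapply(cl, function(x) length(x$members), 0L),
                decreasing = TRUE)
  expect_equal(sizes, c(3L, 2L, 1L))
  for (x in cl) {
    rep_score <- ds$scores$reweighted[ds$scores$decoy == x$representative]
    member_scores <- ds$scores$reweighted[ds$scores$decoy %in% x$members]
    expect_true(all(rep_score <= member_scores))
  }
  # all identical decoys collapse into one cluster
  one <- cluster_decoys(synthetic_decoys(rep(list(c(0, 0, 0)), 5)))
  expect_length(one, 1)
  expect_length(one[[1]]$members, 5)
})

test_that("clustering matches an independent reference on random sets", {
  # reference: straightforward re-implementation with explicit matrices
  reference_cluster <- function(m, ids, rew, radius) {
    unassigned <- rep(TRUE, length(ids))
    out <- list()
    while (any(unassigned)) {
      counts <- rep(-1L, length(ids))
      for (i in which(unassigned)) {
        counts[i] <- sum(m[i, ] <= radius & unassigned)
      }
      c0 <- which.max(counts)
      mem <- which(unassigned & m[c0, ] <= radius)
      ord <- mem[order(rew[mem], ids[mem])]
      out[[length(out) + 1]] <- list(members = sort(ids[mem]),
                                     representative = ids[ord[1]])
      unassigned[mem] <- FALSE
    }
    out
  }
  set.seed(21)
  for (trial in 1:3) {
    n_dec <- sample(10:25, 1)
    offs <- lapply(seq_len(n_dec), function(i) runif(3, -6, 6))
    rew <- round(runif(n_dec, -10, 10), 3)
    ds <- synthetic_decoys(offs, scores = rew)
    got <- cluster_decoys(ds, radius = 2.5)
    ids <- sort(ds$scores$decoy)
    poses <- lapply(ds$decoys[ids], function(d) d$pose)
    m <- pepdock:::decoy_rmsd_matrix(poses)
    want <- reference_cluster(m, ids, ds$scores$reweighted[match(
      ids, ds$scores$decoy)], 2.5)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(sort(got[[k]]$members), want[[k]]$members)
      expect_equal(got[[k]]$representative, want[[k]]$representative)
    }
  }
})

test_that("cluster ranking is ascending with stable tie-breaks", {
  mk <- function(rep, score) structure(
    list(members = rep, center = rep, representative = rep,
         rep_score = score, rank = NA_integer_), class = "decoy_cluster")
  ranked <- rank_clusters(list(mk("c", 3.1), mk("a", -2), mk("b", 0.5)))
  expect_equal(vapply(ranked, function(x) x$rep_score, 0), c(-2, 0.5, 3.1))
  expect_equal(vapply(ranked, function(x) x$rank, 0L), 1:3)
  tied <- rank_clusters(list(mk("z", 1), mk("a", 1)))
  expect_equal(tied[[1]]$representative, "a")
})

test_that("run classification applies the 2 A near-native rule", {
  sys <- toy_fixture()
  offs <- list(c(0.5, 0, 0), c(3.5, 0, 0), c(7, 0, 0), c(10, 0, 0))
  ds <- synthetic_decoys(offs, scores = c(4, 3, 2, 1))
  clusters <- rank_clusters(cluster_decoys(ds, radius = 2))
  rep_ <- classify_run(clusters, ds, sys$native)
  expect_true(rep_$sampled_near_native)
  # the 0.5 A decoy has the worst score, so its cluster ranks last
  expect_equal(rep_$rank_of_first_near_native, 4L)
  expect_equal(rep_$best_irmsd, 0.5, tolerance = 1e-9)
  # a 2.1 A representative alone is not near-native
  ds2 <- synthetic_decoys(list(c(2.1, 0, 0)), scores = 1)
  cl2 <- rank_clusters(cluster_decoys(ds2, radius = 2))
  rep2 <- classify_run(cl2, ds2, sys$native)
  expect_false(rep2$sampled_near_native)
  expect_true(is.na(rep2$rank_of_first_near_native))
  # monotonicity: adding a decoy can only improve the best fields
  ds3 <- synthetic_decoys(c(offs, list(c(0.1, 0, 0))),
                          scores = c(4, 3, 2, 1, 5))
  cl3 <- rank_clusters(cluster_decoys(ds3, radius = 2))
  rep3 <- classify_run(cl3, ds3, sys$native)
  expect_lte(rep3$best_irmsd, rep_$best_irmsd)
  expect_lte(rep3$best_irmsd_top10, rep_$best_irmsd_top10)
})

test_that("the landscape table flags the selection set and threshold", {
  sys <- toy_fixture()
  offs <- lapply(seq_len(12), function(i) c(i / 2, 0, 0))
  ds <- synthetic_decoys(offs, scores = 12:1)
  tab <- landscape_table(ds, sys$native, top_n = 5)
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$in_top500), 5)
  expect_equal(attr(tab, "top500_threshold"),
               max(tab$reweighted[tab$in_top500]))
})
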