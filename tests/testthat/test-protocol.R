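test_that("annealing interpolates 2.0 to 0.6 over the outer cycles", {
  cfg <- protocol_config()
  expect_equal(anneal_temperature(1, cfg), 2.0)
  expect_equal(anneal_temperature(10, cfg), 0.6)
  temps <- vapply(1:10, anneal_temperature, 0, config = cfg)
  expect_true(all(diff(temps) < 0))
  expect_error(anneal_temperature(11, cfg), "range")
})

test_that("prepack reduces clashes without touching the backbone", {
  sys <- toy_fixture()
  w <- score_weights()
  clashed <- sys$native
  clashed$peptide$cen_dist <- pmin(clashed$peptide$cen_dist + 1.5, 4.5)
  clashed$peptide <- pepdock:::rebuild_chain(clashed$peptide)
  before <- score_pose(clashed, w)$e_rep
  packed <- prepack(clashed, w)
  expect_lte(score_pose(packed, w)$e_rep, before)
  bb <- !pepdock:::atom_is_cen(8)
  expect_equal(peptide_world_coords(packed)[bb, ],
               peptide_world_coords(clashed)[bb, ], tolerance = 1e-9)
  # idempotent on a clash-free pose
  again <- prepack(sys$native, w)
  expect_equal(again$peptide$cen_dist, sys$native$peptide$cen_dist)
})

test_that("rigid inner simulation runs 50 proposals, torsions fixed", {
  sys <- toy_fixture()
  cfg <- protocol_config()
  set.seed(17)
  out <- rigid_body_inner_sim(sys$start, T = 2, cfg)
  expect_equal(nrow(out$log), 50)
  expect_true(all(out$log$kind == 0))
  expect_identical(out$pose$peptide$tor, sys$start$peptide$tor)
  expect_lte(out$best_e, out$e_total)
})

test_that("backbone inner simulation leaves the transform bit-identical", {
  sys <- toy_fixture()
  cfg <- protocol_config()
  set.seed(18)
  out <- backbone_inner_sim(sys$start, T = 2, cfg, sys$frags)
  expect_equal(nrow(out$log), 50)
  expect_identical(out$pose$xform$R, sys$start$xform$R)
  expect_identical(out$pose$xform$t, sys$start$xform$t)
})

test_that("backbone move-kind mixture matches the schedule in aggregate", {
  sys <- toy_fixture()
  cfg <- protocol_config()
  set.seed(19)
  logs <- lapply(1:40, function(i) {
    backbone_inner_sim(sys$start, T = 2, cfg, sys$frags)$log
  })
  kinds <- do.call(rbind, logs)$kind
  n <- length(kinds)
  # 8-residue peptide: nonamers excluded, mass renormalized over the rest
  p <- c(small = 0.3, shear = 0.3, trimer = 0.3, pentamer = 0.075) / 0.975
  for (k in 1:4) {
    se <- sqrt(p[k] * (1 - p[k]) / n)
    expect_lt(abs(mean(kinds == k) - p[k]), 4 * se)
  }
  expect_false(any(kinds == 5))
})

test_that("stage Ia runs 10 annealed cycles and returns its best state", {
  sys <- toy_fixture()
  cfg <- protocol_config()
  w <- cfg$weights
  rec_before <- sys$start$receptor$coords
  set.seed(20)
  lo <- lowres_abinitio(sys$start, cfg, sys$frags, log_moves = TRUE)
  expect_equal(nrow(lo$cycles), 10)
  expect_equal(nrow(lo$log), 10 * 100)
  expect_equal(as.integer(table(lo$log$cycle)), rep(100L, 10))
  expect_identical(lo$pose$receptor$coords, rec_before)
  expect_equal(score_pose(lo$pose, w)$e_total, lo$best_e, tolerance = 1e-6)
  # annealed descent tendency over seeds
  e0 <- score_pose(prepack(sys$start, w), w)$e_total
  improved <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    lowres_abinitio(sys$start, cfg, sys$frags)$best_e <= e0
  }, TRUE)
  expect_gte(mean(improved), 0.95)
})

test_that("refinement ramps weights back to 1 and stays near a minimum", {
  sys <- toy_fixture()
  cfg <- protocol_config()
  set.seed(21)
  rf <- refine(sys$native, cfg)
  expect_equal(rf$cycles$f_rep[cfg$n_refine], 1)
  expect_equal(rf$cycles$f_att[cfg$n_refine], 1)
  expect_equal(rf$cycles$f_rep[1], 0.1)
  expect_equal(rf$cycles$f_att[1], 2.0)
  # the planted native stays in its basin across seeds (the canonical
  # torsions sit ~1 A from the surrogate's relaxed optimum, so refinement
  # drifts that far and no further)
  drift <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    peptide_backbone_rmsd(refine(sys$native, cfg)$pose, sys$native)
  }, 0)
  expect_gte(mean(drift < 2), 0.9)
})

test_that("decoy generation is deterministic with recorded seeds", {
  sys <- toy_fixture()
  cfg <- protocol_config(nstruct = 8, seed = 404)
  ds1 <- generate_decoys(sys$start, cfg, sys$frags)
  expect_length(ds1$decoys, 8)
  expect_equal(anyDuplicated(ds1$scores$seed), 0)
  ds2 <- generate_decoys(sys$start, cfg, sys$frags)
  expect_identical(ds1$scores, ds2$scores)
  # stored breakdown is reproducible from the stored pose
  rec <- ds1$decoys[[3]]
  again <- score_pose(rec$pose, cfg$weights)
  expect_equal(again$e_total, rec$breakdown$e_total, tolerance = 1e-6)
  expect_equal(again$reweighted, rec$breakdown$reweighted, tolerance = 1e-6)
  # receptor immutability through the full run
  expect_identical(rec$pose$receptor$coords, sys$start$receptor$coords)
  expect_warning(empty <- generate_decoys(sys$start,
                                          protocol_config(nstruct = 0),
                                          sys$frags), "no decoys")
  expect_length(empty$decoys, 0)
})

test_that("score tables and decoy PDBs are written on request", {
  sys <- toy_fixture()
  out <- tempfile()
  cfg <- protocol_config(nstruct = 2, seed = 7)
  ds <- generate_decoys(sys$start, cfg, sys$frags, out_dir = out)
  expect_true(file.exists(file.path(out, "score.sc")))
  tab <- read_score_table(file.path(out, "score.sc"))
  expect_equal(tab$decoy, ds$scores$decoy)
  expect_true(all(file.exists(file.path(out, paste0(ds$scores$decoy,
                                                    ".pdb")))))
})
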