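test_that("move-kind frequencies follow the schedule mixture", {
  set.seed(42)
  sch <- move_schedule()
  n <- 1e5
  kinds <- choose_backbone_move(sch, peptide_len = 12, n = n)
  p_hat <- table(factor(kinds, c("small", "shear", "trimer", "pentamer",
                                 "nonamer"))) / n
  expected <- c(small = 0.3, shear = 0.3, trimer = 0.3, pentamer = 0.075,
                nonamer = 0.025)
  for (k in names(expected)) {
    se <- sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(p_hat[[k]] - expected[[k]]), 3 * se)
  }
  expect_lt(abs(sum(p_hat[c("small", "shear")]) - 0.6),
            3 * sqrt(0.6 * 0.4 / n))
})

test_that("fragment kinds too long for the peptide are excluded", {
  set.seed(7)
  sch <- move_schedule()
  expect_false("nonamer" %in% choose_backbone_move(sch, 5, 2000))
  k3 <- choose_backbone_move(sch, 3, 2000)
  expect_true(all(k3 %in% c("small", "shear", "trimer")))
  expect_error(choose_backbone_move(sch, 2), "at least 3")
  # redistributed mass keeps proportions among the remaining kinds
  k5 <- choose_backbone_move(sch, 5, 5e4)
  frac_small <- mean(k5 == "small")
  expect_lt(abs(frac_small - 0.3 / 0.975), 3 * sqrt(0.31 * 0.69 / 5e4))
})

test_that("small move perturbs exactly one residue and keeps geometry", {
  set.seed(1)
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  mv <- small_move(ch, move_schedule(), T = 2)
  if (!mv$rejected) {
    changed <- which(rowSums(mv$chain$tor != ch$tor) > 0)
    expect_equal(changed, mv$residue)
    expect_true(all(mv$chain$tor[-mv$residue, ] == ch$tor[-mv$residue, ]))
    ca1 <- mv$chain$local[5 * (0:7) + 2, ]
    expect_equal(unname(sqrt(rowSums(diff(ca1)^2))),
                 rep(oracle_ca_ca_distance(), 7), tolerance = 1e-6)
  } else {
    expect_identical(mv$chain$tor, ch$tor)
  }
})

test_that("shear move pairs opposite-sign rotations on adjacent torsions", {
  set.seed(3)
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  for (trial in 1:20) {
    mv <- shear_move(ch, move_schedule(), T = 2)
    if (mv$rejected) next
    i <- mv$residue
    d_psi <- mv$chain$tor[i - 1, 2] - ch$tor[i - 1, 2]
    d_phi <- mv$chain$tor[i, 1] - ch$tor[i, 1]
    expect_equal(unname(d_phi), unname(-d_psi), tolerance = 1e-12)
    others <- setdiff(1:8, c(i - 1, i))
    expect_true(all(mv$chain$tor[others, ] == ch$tor[others, ]))
  }
})

test_that("shear moves displace the downstream chain less than small moves", {
  # paired construction: identical delta applied as shear vs naive phi-only
  ch <- test_chain("AKLAELAKAKLA", helix_torsions(12))
  set.seed(11)
  disp <- function(tor) {
    moved <- set_torsions(ch, tor)
    ca0 <- ch$local[5 * (0:11) + 2, ]
    ca1 <- moved$local[5 * (0:11) + 2, ]
    mean(sqrt(rowSums((ca1 - ca0)[8:12, ]^2)))  # >= 2 residues downstream
  }
  d_shear <- d_small <- numeric(200)
  for (k in 1:200) {
    i <- sample(3:6, 1)
    delta <- runif(1, -30, 30)
    tor_sh <- ch$tor
    tor_sh[i - 1, 2] <- tor_sh[i - 1, 2] + delta
    tor_sh[i, 1] <- tor_sh[i, 1] - delta
    tor_sm <- ch$tor
    tor_sm[i - 1, 2] <- tor_sm[i - 1, 2] + delta
    d_shear[k] <- disp(tor_sh)
    d_small[k] <- disp(tor_sm)
  }
  expect_lt(mean(d_shear), mean(d_small))
})

test_that("the Ramachandran screen suppresses unfavorable proposals", {
  # paired simulation: screening on vs off (w_rama = 0 disables the bias)
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  sch <- move_schedule(torsion_mag = 120, t_rama = 0.6)
  frac_bad <- function(weights, seed) {
    set.seed(seed)
    bad <- 0; acc <- 0
    for (k in 1:2000) {
      mv <- small_move(ch, sch, T = 2, weights = weights)
      if (mv$rejected) next
      acc <- acc + 1
      lev <- rama_energy(mv$chain$tor[mv$residue, 1],
                         mv$chain$tor[mv$residue, 2])
      if (lev >= 3) bad <- bad + 1
    }
    bad / acc
  }
  expect_lt(frac_bad(score_weights(), 5),
            frac_bad(score_weights(w_rama = 0), 5))
})

test_that("Metropolis acceptance follows exp(-dE/T)", {
  expect_true(metropolis(-5, 0.1))
  expect_true(metropolis(0, 1))
  expect_error(metropolis(1, 0), "positive")
  set.seed(8)
  n <- 1e5
  acc <- sum(vapply(seq_len(n), function(i) metropolis(1, 1), TRUE))
  p <- exp(-1)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
  set.seed(9)
  expect_false(any(vapply(1:1e4, function(i) metropolis(1e9, 1), TRUE)))
})

test_that("rigid-body move magnitudes average to the schedule values", {
  set.seed(12)
  xf <- rigid_xform()
  n <- 2e4
  mags <- vapply(seq_len(n), function(i) {
    prop <- rigid_body_move(xf, move_schedule())
    sqrt(sum(prop$t^2))
  }, 0)
  se <- sd(mags) / sqrt(n)
  expect_lt(abs(mean(mags) - 1), 3 * se)
})

test_that("a rigid move composed with its inverse returns the start", {
  set.seed(2)
  xf <- rigid_xform(rot_axis_angle(c(0, 1, 1), 25), c(3, 1, -2))
  prop <- rigid_body_move(xf, move_schedule())
  back <- xform_compose(xform_compose(prop, xform_inverse(prop)), xf)
  expect_equal(back$R, xf$R, tolerance = 1e-9)
  expect_equal(back$t, xf$t, tolerance = 1e-9)
  # rigid moves preserve peptide internal distances
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  a <- xform_apply(xf, ch$local)
  b <- xform_apply(prop, ch$local)
  expect_equal(as.numeric(dist(b)), as.numeric(dist(a)), tolerance = 1e-9)
})

test_that("start perturbation has the stated Gaussian scales", {
  xf <- rigid_xform()
  set.seed(4)
  same <- random_start_perturbation(xf, trans_sigma = 0, rot_sigma = 0)
  expect_equal(same$t, xf$t, tolerance = 1e-12)
  expect_equal(same$R, xf$R, tolerance = 1e-12)
  set.seed(4)
  moved <- random_start_perturbation(xf)
  expect_gt(sqrt(sum((moved$t - xf$t)^2)), 0)
  # RMS translation magnitude equals 3 Angstrom
  set.seed(6)
  mags2 <- vapply(1:2e4, function(i) {
    sum(random_start_perturbation(xf)$t^2)
  }, 0)
  expect_lt(abs(sqrt(mean(mags2)) - 3), 0.1)
})

test_that("identical seeds give bit-identical proposal trajectories", {
  sys <- toy_fixture()
  cfg <- protocol_config()
  run <- function() {
    set.seed(31)
    backbone_inner_sim(sys$start, T = 1.2, cfg, sys$frags)
  }
  a <- run(); b <- run()
  expect_identical(a$log, b$log)
  expect_identical(a$pose$peptide$tor, b$pose$peptide$tor)
})
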