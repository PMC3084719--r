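test_that("angles wrap into (-180, 180]", {
  expect_equal(wrap_angle(190), -170)
  expect_equal(wrap_angle(-180), 180)
  expect_equal(wrap_angle(135), 135)
  expect_equal(wrap_angle(c(360, 540, -361)), c(0, 180, -1))
})

test_that("extended chain geometry matches the independent planar oracle", {
  ch <- test_chain("AKLAELAK")
  ca <- ch$local[5 * (0:7) + 2, ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-9)
  expect_equal(unname(d[1]), oracle_ca_ca_distance(), tolerance = 1e-6)
})

test_that("torsions round-trip through the built coordinates", {
  tor <- cbind(phi = c(NA, -72, -65, 140, -58, -60, -100, 135),
               psi = c(150, -40, -42, 155, -47, -38, 120, NA),
               omega = c(180, 180, 175, 180, 180, 178, 180, NA))
  ch <- test_chain("AKLAELAK", tor)
  xyz <- ch$local
  g <- function(i, k) xyz[5 * (i - 1) + k, ]
  for (i in 2:8) {
    expect_equal(dihedral_angle(g(i - 1, 3), g(i, 1), g(i, 2), g(i, 3)),
                 unname(tor[i, "phi"]), tolerance = 1e-6)
  }
  for (i in 1:7) {
    expect_equal(dihedral_angle(g(i, 1), g(i, 2), g(i, 3), g(i + 1, 1)),
                 unname(tor[i, "psi"]), tolerance = 1e-6)
  }
})

test_that("rebuild is idempotent and periodic in the torsions", {
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  ch2 <- torsions_to_coords(ch)
  expect_equal(ch2$local, ch$local, tolerance = 1e-10)
  tor <- ch$tor
  tor[4, 1] <- tor[4, 1] + 360
  tor[6, 2] <- tor[6, 2] - 720
  ch3 <- set_torsions(ch, tor)
  expect_equal(ch3$local, ch$local, tolerance = 1e-9)
})

test_that("torsion edits preserve ideal bond geometry", {
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  tor <- ch$tor
  tor[3, 1:2] <- c(-120, 140)
  ch <- set_torsions(ch, tor)
  geom <- ideal_geometry()
  xyz <- ch$local
  for (i in 1:8) {
    N <- xyz[5 * (i - 1) + 1, ]; CA <- xyz[5 * (i - 1) + 2, ]
    C <- xyz[5 * (i - 1) + 3, ]; O <- xyz[5 * (i - 1) + 4, ]
    expect_equal(sqrt(sum((CA - N)^2)), unname(geom["n_ca"]),
                 tolerance = 1e-6)
    expect_equal(sqrt(sum((C - CA)^2)), unname(geom["ca_c"]),
                 tolerance = 1e-6)
    expect_equal(sqrt(sum((O - C)^2)), unname(geom["c_o"]),
                 tolerance = 1e-6)
    if (i < 8) {
      N2 <- xyz[5 * i + 1, ]
      expect_equal(sqrt(sum((N2 - C)^2)), unname(geom["c_n"]),
                   tolerance = 1e-6)
    }
  }
})

test_that("set_extended gives the canonical +135/-135 conformation", {
  ch <- set_extended(test_chain("AKLAELAK", helix_torsions(8)))
  expect_true(all(ch$tor[, "phi"] == 135))
  expect_true(all(ch$tor[, "psi"] == -135))
  expect_true(all(ch$tor[, "omega"] == 180))
  expect_equal(torsion_space_rmsd(ch, ch), 0)
})

test_that("rigid transforms preserve internal distances", {
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  xf <- rigid_xform(rot_axis_angle(c(1, 2, 3), 77), c(4, -2, 9))
  moved <- xform_apply(xf, ch$local)
  d0 <- dist(ch$local)
  d1 <- dist(moved)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  # composition with the inverse is the identity
  id <- xform_compose(xform_inverse(xf), xf)
  expect_equal(id$R, diag(3), tolerance = 1e-9)
  expect_equal(id$t, c(0, 0, 0), tolerance = 1e-9)
})

test_that("anchor rooting keeps the anchor residue fixed under edits", {
  ch <- pepdock:::pep_chain("AKLAELAK", anchor = 5)
  triad <- ch$local[21:23, ]
  tor <- ch$tor
  tor[2, 1:2] <- c(-70, -35)
  tor[8, 1] <- -120
  ch2 <- set_torsions(ch, tor)
  expect_equal(ch2$local[21:23, ], triad, tolerance = 1e-9)
  # anchor = 1 leaves the first-residue frame convention intact
  ch1 <- pepdock:::pep_chain("AKL")
  expect_equal(unname(ch1$local[1, ]), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(ch1$local[2, 2:3]), c(0, 0), tolerance = 1e-9)
})

test_that("PDB round trip preserves coordinates and torsions", {
  sys <- toy_fixture()
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys$native, path)
  pose2 <- read_pdb(path, receptor_chain = "A", peptide_chain = "B")
  expect_equal(chain_length(pose2$peptide), 8)
  # backbone coordinates to PDB precision
  keep <- !pepdock:::atom_is_cen(8)
  expect_equal(peptide_world_coords(pose2)[keep, ],
               peptide_world_coords(sys$native)[keep, ], tolerance = 2e-3,
               ignore_attr = TRUE)
  # defined torsions to 1e-2 degrees (PDB coordinate precision limits)
  def <- pose2$peptide$defined[, 1:2] & sys$native$peptide$defined[, 1:2]
  expect_equal(wrap_angle(pose2$peptide$tor[, 1:2][def]),
               wrap_angle(sys$native$peptide$tor[, 1:2][def]),
               tolerance = 1e-2)
  # write then read again: torsions stable to 1e-3 degrees
  path2 <- tempfile(fileext = ".pdb")
  write_pdb(pose2, path2)
  pose3 <- read_pdb(path2, receptor_chain = "A", peptide_chain = "B")
  expect_equal(wrap_angle(pose3$peptide$tor[, 1:2][def]),
               wrap_angle(pose2$peptide$tor[, 1:2][def]), tolerance = 1e-3)
  # no CEN records by default; present with write_cen
  expect_false(any(grepl("CEN", readLines(path))))
  path3 <- tempfile(fileext = ".pdb")
  write_pdb(sys$native, path3, write_cen = TRUE)
  expect_true(any(grepl("CEN", readLines(path3))))
})

test_that("glycine receives an extrapolated C-beta centroid on read", {
  ch <- test_chain("AGLAG", helix_torsions(5))
  rec <- toy_fixture()$native$receptor
  pose <- complex_pose(rec, ch, rigid_xform(diag(3), c(50, 0, 0)))
  path <- tempfile(fileext = ".pdb")
  write_pdb(pose, path)
  pose2 <- read_pdb(path, "A", "B")
  # backbone-only input: all CENs sit at the ideal extrapolated site
  cen2 <- peptide_world_coords(pose2)[pepdock:::atom_is_cen(5), ]
  cen1 <- peptide_world_coords(pose)[pepdock:::atom_is_cen(5), ]
  expect_equal(cen2, cen1, tolerance = 5e-3, ignore_attr = TRUE)
})

test_that("reading rejects malformed inputs", {
  sys <- toy_fixture()
  path <- tempfile(fileext = ".pdb")
  write_pdb(sys$native, path)
  expect_error(read_pdb(path, "A", "Q"), "not found")
  ch <- test_chain("AKL")
  expect_error(pepdock:::pep_chain(""), "empty")
})

test_that("place_at_anchor superposes the anchor residue on the native", {
  sys <- toy_fixture()
  start <- make_start_structure(sys$native, anchor = 3, seed = 1)
  expect_equal(start$meta$anchor, 3)
  rows <- 5 * 2 + 1:3
  a <- peptide_world_coords(start)[rows, ]
  b <- peptide_world_coords(sys$native)[rows, ]
  expect_lt(sqrt(sum((a[2, ] - b[2, ])^2)), 0.2)
  # the native peptide itself superposes exactly everywhere
  self <- place_at_anchor(sys$native, sys$native, 4)
  expect_equal(peptide_world_coords(self),
               peptide_world_coords(sys$native), tolerance = 1e-6)
  expect_error(place_at_anchor(start, sys$native, 99), "range")
})
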