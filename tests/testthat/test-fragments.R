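make_source <- function(id, tor, seq = NULL) {
  n <- nrow(tor)
  if (is.null(seq)) seq <- rep("A", n)
  pepdock:::new_frag_source(id, seq, tor)
}

ideal_helix_tor <- function(n) {
  tor <- cbind(phi = rep(-60, n), psi = rep(-45, n), omega = rep(180, n))
  tor[1, 1] <- NA
  tor[n, 2:3] <- NA
  tor
}

test_that("torsion-bin secondary-structure labels follow the stated rule", {
  expect_equal(ss_from_torsions(-60, -45), "H")
  expect_equal(ss_from_torsions(-120, 120), "E")
  expect_equal(ss_from_torsions(-120, -175), "E")  # psi in (-180, -170)
  expect_equal(ss_from_torsions(60, 50), "C")
  expect_equal(ss_from_torsions(-100, -45), "C")   # open interval boundary
})

test_that("candidate extraction respects length, termini and chain breaks", {
  src <- make_source("helix12", ideal_helix_tor(12))
  w3 <- extract_candidate_windows(src, 3)
  # windows cannot use the undefined terminal torsions
  expect_length(w3, 8)
  expect_true(all(vapply(w3, function(f) all(f$ss == "H"), TRUE)))
  expect_warning(expect_length(extract_candidate_windows(
    make_source("tiny", ideal_helix_tor(4)), 5), 0))
  # a chain break removes spanning windows
  tor <- ideal_helix_tor(12)
  tor[6, 2:3] <- NA  # break between residues 6 and 7
  tor[7, 1] <- NA
  wb <- extract_candidate_windows(make_source("broken", tor), 3)
  starts <- vapply(wb, function(f) f$start, 0L)
  expect_true(all(starts %in% c(2, 3, 4, 8, 9, 10)))
})

test_that("fragment scoring combines sequence and SS terms as stated", {
  tor <- ideal_helix_tor(5)
  frag <- extract_candidate_windows(
    make_source("s", tor, seq = c("A", "K", "L", "A", "K")), 3)[[1]]
  # perfect prediction for H everywhere, identical sequence
  ss_certain <- ss_prediction(matrix(rep(c(1, 0, 0), each = 3), 3, 3))
  best <- score_fragment(frag, frag$seq, ss_certain)
  # any mismatching sequence scores no higher
  worse <- score_fragment(frag, c("W", "W", "W"), ss_certain)
  expect_gt(best, worse)
  # with zero SS weight the ranking depends only on the sequence term
  s1 <- score_fragment(frag, frag$seq, ss_certain, w_seq = 1, w_ss = 0)
  B <- pepdock:::blosum62_matrix()
  expect_equal(s1, mean(B[cbind(frag$seq, frag$seq)]))
  expect_error(score_fragment(frag, c("A", "A"), ss_certain[1:2, ]),
               "length")
})

test_that("picker fills categories to quota with deterministic tie-breaks", {
  sys <- toy_fixture()
  pool <- unlist(lapply(c(3, 5), function(L) {
    extract_candidate_windows(sys$sources, L)
  }), recursive = FALSE)
  lib <- pick_fragments("AKLAELAK", sys$ss_pred, pool)
  counts <- library_counts(lib)
  expect_equal(unname(counts[c("H", "E", "C")]), c(500, 500, 500))
  expect_equal(unname(counts["total"]), 1500)
  # no nonamers for a short query even if requested lengths include them
  expect_false(9 %in% lib$lengths)
  # determinism: identical library from an identical call
  lib2 <- pick_fragments("AKLAELAK", sys$ss_pred, pool)
  p1 <- tempfile(); p2 <- tempfile()
  write_fragment_library(lib, p1)
  write_fragment_library(lib2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("an insufficient pool keeps everything with a warning", {
  src <- make_source("helix12", ideal_helix_tor(12))
  pool <- extract_candidate_windows(src, 3)  # 8 H candidates, no E/C
  expect_warning(lib <- pick_fragments("AKLAE", ss_prediction(
    matrix(1 / 3, 5, 3)), pool), "available|candidates")
  expect_equal(unname(library_counts(lib)["H"]), 8)
})

test_that("fragment insertion replaces exactly the covered window", {
  ch <- test_chain("AKLAELAK", helix_torsions(8))
  src <- make_source("self", rbind(ch$tor))
  frag <- extract_candidate_windows(src, 3)[[2]]  # starts at position 2
  same <- insert_fragment(ch, frag, start_pos = frag$start)
  expect_equal(same$tor, ch$tor, tolerance = 1e-12)
  other <- structure(list(length = 3L,
                          tor = cbind(c(-120, -120, -120), c(120, 120, 120),
                                      c(180, 180, 180)),
                          ss = c("E", "E", "E"), seq = c("A", "A", "A"),
                          source = "x", start = 1L, score = 0),
                     class = "pep_fragment")
  ins <- insert_fragment(ch, other, start_pos = 1)
  expect_equal(unname(ins$tor[1:3, 1]), rep(-120, 3))
  expect_equal(ins$tor[4:8, ], ch$tor[4:8, ])
  long <- other; long$length <- 9L
  expect_error(insert_fragment(test_chain("AKLAE"), long), "longer")
})

test_that("the fragment text format round-trips bit-exactly", {
  sys <- toy_fixture()
  pool <- extract_candidate_windows(sys$sources, 3)
  lib <- pick_fragments("AKLAELAK", sys$ss_pred, pool[1:200],
                        per_category = 20)
  p1 <- tempfile()
  write_fragment_library(lib, p1)
  lib2 <- read_fragment_library(p1)
  p2 <- tempfile()
  write_fragment_library(lib2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(lib2$frags[[1]]$tor, lib$frags[[1]]$tor,
               ignore_attr = TRUE)
})

test_that("the propensity predictor returns a valid prediction", {
  pred <- predict_ss_propensity("AELKAAAE")
  expect_s3_class(pred, "ss_prediction")
  expect_equal(rowSums(pred), rep(1, 8), tolerance = 1e-9)
  # helix formers leave H as the dominant state
  expect_true(mean(pred[, "H"]) > mean(pred[, "E"]))
  path <- tempfile()
  write_ss_prediction(pred, path)
  back <- read_ss_prediction(path)
  expect_equal(unclass(back), unclass(pred), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(ss_prediction(matrix(0.5, 4, 3)), "sum to 1")
})

test_that("source structures survive a PDB round trip", {
  sys <- toy_fixture()
  dir <- tempfile()
  dir.create(dir)
  write_source_pdb(sys$sources[[1]], file.path(dir, "src.pdb"))
  back <- read_source_structure(file.path(dir, "src.pdb"))
  def <- !is.na(sys$sources[[1]]$tor) & !is.na(back$tor)
  expect_lt(max(abs(wrap_angle(back$tor[def] - sys$sources[[1]]$tor[def]))),
            0.1)
})
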