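# Bundled constants: ideal backbone geometry, per-residue centroid
# parameters, and the coarse Ramachandran level table.

#' Ideal polypeptide backbone geometry
#'
#' Bond lengths (Angstrom) and bond angles (degrees) used whenever peptide
#' coordinates are rebuilt from torsions. Values are the standard
#' Engh-Huber-style ideal geometry for a trans polypeptide backbone.
#'
#' @return Named numeric vector with elements `n_ca`, `ca_c`, `c_n`, `c_o`
#'   (lengths) and `ang_c_n_ca`, `ang_n_ca_c`, `ang_ca_c_n`, `ang_ca_c_o`
#'   (angles).
#' @export
ideal_geometry <- function() {
  c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
    ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
    ang_ca_c_o = 120.8)
}

# radius of backbone atoms (N, CA, C, O) in the unified-sphere model
BACKBONE_RADIUS <- 1.6

# Per-residue side-chain centroid parameters: distance of the CEN
# pseudo-atom from CA along the ideal C-beta direction, and its sphere
# radius, by size class (small / medium / large).
AA_TABLE <- local({
  aa <- c("G", "A", "S", "C",
          "T", "P", "V", "N", "D", "L", "I", "M", "E", "Q",
          "F", "Y", "W", "R", "K", "H")
  cls <- c(rep("small", 4), rep("medium", 10), rep("large", 6))
  dist <- c(small = 1.5, medium = 2.3, large = 3.0)[cls]
  rad <- c(small = 1.4, medium = 1.8, large = 2.2)[cls]
  data.frame(aa = aa, class = cls, cen_dist = as.numeric(dist),
             cen_rad = as.numeric(rad), stringsAsFactors = FALSE)
})

aa_lookup <- function(seq) {
  idx <- match(toupper(seq), AA_TABLE$aa)
  if (anyNA(idx)) {
    # unknown residue types fall back to the medium class
    idx[is.na(idx)] <- match("T", AA_TABLE$aa)
  }
  AA_TABLE[idx, , drop = FALSE]
}

rama_class_of <- function(seq) {
  ifelse(toupper(seq) == "G", 1L, ifelse(toupper(seq) == "P", 2L, 0L))
}

#' Coarse Ramachandran level table
#'
#' 20 x 20 degree phi/psi bins assigned one of three levels (favored 0,
#' allowed 1, disallowed 3) for three residue classes: generic, glycine and
#' proline. The glycine table is symmetric under (phi, psi) -> (-phi, -psi).
#'
#' @return A list of three 18 x 18 matrices named `generic`, `glycine`,
#'   `proline`; rows index phi bins, columns psi bins, both over
#'   `[-180, 180)` in 20 degree steps.
#' @export
rama_table <- function() {
  centers <- seq(-170, 170, by = 20)
  in_box <- function(x, lo, hi) x >= lo & x < hi
  gen_fav <- matrix(FALSE, 18, 18)
  for (i in 1:18) for (j in 1:18) {
    p <- centers[i]; s <- centers[j]
    helix <- in_box(p, -100, -40) && in_box(s, -60, 0)
    sheet <- in_box(p, -160, -60) && (in_box(s, 100, 180) ||
                                        in_box(s, -180, -160))
    gen_fav[i, j] <- helix || sheet
  }
  neighbor_of <- function(fav) {
    out <- matrix(FALSE, 18, 18)
    for (i in 1:18) for (j in 1:18) {
      for (di in -1:1) for (dj in -1:1) {
        ii <- ((i - 1 + di) %% 18) + 1
        jj <- ((j - 1 + dj) %% 18) + 1
        if (fav[ii, jj]) out[i, j] <- TRUE
      }
    }
    out
  }
  levels_from <- function(fav, extra_allowed = NULL) {
    allowed <- neighbor_of(fav)
    if (!is.null(extra_allowed)) allowed <- allowed | extra_allowed
    m <- matrix(3, 18, 18)
    m[allowed] <- 1
    m[fav] <- 0
    m
  }
  # left-handed helix region is allowed (not favored) for the generic class
  lh <- matrix(FALSE, 18, 18)
  for (i in 1:18) for (j in 1:18) {
    lh[i, j] <- in_box(centers[i], 40, 100) && in_box(centers[j], 0, 80)
  }
  generic <- levels_from(gen_fav, lh)
  # glycine: symmetrized generic levels
  glycine <- matrix(3, 18, 18)
  for (i in 1:18) for (j in 1:18) {
    glycine[i, j] <- min(generic[i, j], generic[19 - i, 19 - j])
  }
  # proline: phi restricted near -60
  pro_fav <- matrix(FALSE, 18, 18)
  for (i in 1:18) for (j in 1:18) {
    p <- centers[i]; s <- centers[j]
    pro_fav[i, j] <- in_box(p, -80, -40) &&
      (in_box(s, -60, 20) || in_box(s, 100, 180))
  }
  proline <- levels_from(pro_fav)
  list(generic = generic, glycine = glycine, proline = proline)
}

# flattened copy for the C++ scorer: class-major, then phi bin, then psi bin
rama_table_flat <- function(tab = rama_table()) {
  as.numeric(c(t(tab$generic), t(tab$glycine), t(tab$proline)))
}

rama_bin_index <- function(ang) {
  a <- (ang + 180) %% 360
  i <- floor(a / 20) + 1
  pmin(i, 18L)
}
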