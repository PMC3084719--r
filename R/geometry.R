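# Angles, rotations, rigid-body transforms and least-squares superposition.

#' Wrap an angle into (-180, 180]
#'
#' @param deg Numeric vector of angles in degrees.
#' @return Angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_angle(190)   # -170
#' wrap_angle(-180)  # 180
#' @export
wrap_angle <- function(deg) {
  out <- deg - 360 * ceiling((deg - 180) / 360)
  out[out == -180] <- 180
  out
}

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 Numeric xyz triples.
#' @return Signed dihedral in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  wrap_angle(cpp_dihedral(as.numeric(p1), as.numeric(p2),
                          as.numeric(p3), as.numeric(p4)))
}

#' Rotation matrix about an axis
#'
#' @param axis Numeric xyz direction (need not be normalized).
#' @param deg Rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rot_axis_angle <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  c_ <- cos(a); s_ <- sin(a); t_ <- 1 - c_
  x <- u[1]; y <- u[2]; z <- u[3]
  matrix(c(t_ * x * x + c_, t_ * x * y - s_ * z, t_ * x * z + s_ * y,
           t_ * x * y + s_ * z, t_ * y * y + c_, t_ * y * z - s_ * x,
           t_ * x * z - s_ * y, t_ * y * z + s_ * x, t_ * z * z + c_),
         nrow = 3, byrow = TRUE)
}

#' Rigid-body transform
#'
#' A proper rotation plus translation mapping peptide-local coordinates into
#' the receptor (world) frame: `world = R %*% local + t`.
#'
#' @param R 3 x 3 proper rotation matrix (det +1).
#' @param t Length-3 translation in Angstrom.
#' @return Object of class `rigid_xform`.
#' @export
rigid_xform <- function(R = diag(3), t = c(0, 0, 0)) {
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (abs(det(R) - 1) > 1e-9 || max(abs(t(R) %*% R - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = R, t = as.numeric(t)), class = "rigid_xform")
}

#' @export
print.rigid_xform <- function(x, ...) {
  cat("rigid_xform: translation", sprintf("%.3f", x$t), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xf A `rigid_xform`.
#' @param coords m x 3 coordinate matrix (rows are points).
#' @return Transformed m x 3 matrix.
#' @export
xform_apply <- function(xf, coords) {
  sweep(coords %*% t(xf$R), 2, xf$t, "+")
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b `rigid_xform` objects.
#' @return The composite transform `x -> a(b(x))`.
#' @export
xform_compose <- function(a, b) {
  rigid_xform(reorthonormalize(a$R %*% b$R), as.numeric(a$R %*% b$t + a$t))
}

#' Invert a rigid transform
#' @param xf A `rigid_xform`.
#' @return The inverse transform.
#' @export
xform_inverse <- function(xf) {
  rigid_xform(t(xf$R), as.numeric(-t(xf$R) %*% xf$t))
}

# project a near-rotation back onto SO(3)
reorthonormalize <- function(R) {
  s <- svd(R)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the rigid transform minimizing the RMSD between `P` (mobile) and
#' `Q` (fixed), i.e. `R %*% p + t ~ q`.
#'
#' @param P,Q m x 3 coordinate matrices of paired points.
#' @return A `rigid_xform` mapping `P` onto `Q`.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_xform(R, as.numeric(cq - R %*% cp))
}

rmsd_xyz <- function(A, B) {
  sqrt(mean(rowSums((A - B)^2)))
}
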