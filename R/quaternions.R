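## Vectorised unit-quaternion algebra. Quaternions are stored row-wise as
## n x 4 numeric matrices with columns (w, x, y, z); a single rotation is a
## 1 x 4 matrix (or a length-4 vector, promoted on entry). The rotation
## matrix R(q) is the active rotation that carries the sample frame onto the
## crystal frame, so the crystal c-axis expressed in sample coordinates is
## R(q) %*% c(0, 0, 1).

.asQuatMatrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1L)
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("quaternions must have 4 columns (w, x, y, z)")
  storage.mode(q) <- "double"
  q
}

#' Normalise quaternions to unit length
#'
#' @param q numeric matrix (n x 4), columns (w, x, y, z).
#' @return n x 4 matrix of unit quaternions.
#' @keywords internal
quatNormalize <- function(q) {
  q <- .asQuatMatrix(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(!is.finite(nrm)) || any(nrm < 1e-300))
    stop("cannot normalise zero or non-finite quaternion")
  q / nrm
}

#' Canonicalise quaternion sign
#'
#' q and -q encode the same rotation; the representative with w >= 0 is
#' returned (ties w == 0 resolved by the first non-zero component >= 0) so
#' that hashing and averaging are stable.
#'
#' @param q n x 4 quaternion matrix.
#' @return n x 4 matrix with canonical signs.
#' @export
quatCanonical <- function(q) {
  q <- .asQuatMatrix(q)
  flip <- q[, 1L] < 0
  zw <- q[, 1L] == 0
  if (any(zw)) {
    ## w == 0: use first non-zero of (x, y, z)
    sub <- q[zw, , drop = FALSE]
    s <- sign(sub[, 2L])
    s[s == 0] <- sign(sub[s == 0, 3L])
    s[s == 0] <- sign(sub[s == 0, 4L])
    flip[zw] <- s < 0
  }
  q[flip, ] <- -q[flip, , drop = FALSE]
  q
}

#' Quaternion (Hamilton) product
#'
#' Row-wise product a * b; either argument may have one row, which is
#' recycled. Composition matches matrix composition:
#' R(quatMultiply(a, b)) == R(a) %*% R(b).
#'
#' @param a,b quaternion matrices (n x 4 or 1 x 4).
#' @return n x 4 matrix of products.
#' @export
quatMultiply <- function(a, b) {
  a <- .asQuatMatrix(a); b <- .asQuatMatrix(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  w <- a[,1]*b[,1] - a[,2]*b[,2] - a[,3]*b[,3] - a[,4]*b[,4]
  x <- a[,1]*b[,2] + a[,2]*b[,1] + a[,3]*b[,4] - a[,4]*b[,3]
  y <- a[,1]*b[,3] - a[,2]*b[,4] + a[,3]*b[,1] + a[,4]*b[,2]
  z <- a[,1]*b[,4] + a[,2]*b[,3] - a[,3]*b[,2] + a[,4]*b[,1]
  cbind(w = w, x = x, y = y, z = z)
}

#' Quaternion conjugate (rotation inverse for unit quaternions)
#' @param q n x 4 quaternion matrix.
#' @return n x 4 matrix.
#' @export
quatConjugate <- function(q) {
  q <- .asQuatMatrix(q)
  q[, 2:4] <- -q[, 2:4, drop = FALSE]
  q
}

#' Quaternion from axis and angle
#'
#' @param axis length-3 vector (normalised internally) or n x 3 matrix.
#' @param angleDeg rotation angle(s) in degrees.
#' @return n x 4 unit quaternion matrix.
#' @export
quatFromAxisAngle <- function(axis, angleDeg) {
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 1L)
  axis <- as.matrix(axis)
  if (ncol(axis) != 3L) stop("axis must have 3 components")
  n <- max(nrow(axis), length(angleDeg))
  if (nrow(axis) == 1L) axis <- axis[rep(1L, n), , drop = FALSE]
  angleDeg <- rep_len(angleDeg, n)
  nrm <- sqrt(rowSums(axis^2))
  if (any(nrm < 1e-300)) stop("axis must be non-zero")
  axis <- axis / nrm
  half <- angleDeg * pi / 360
  cbind(w = cos(half), axis * sin(half))
}

#' Rotation angle of quaternion(s), in degrees
#'
#' Smallest equivalent angle in [0, 180], i.e. the angle of q after sign
#' canonicalisation.
#'
#' @param q n x 4 quaternion matrix.
#' @return numeric vector of angles (degrees).
#' @export
quatAngleDeg <- function(q) {
  q <- .asQuatMatrix(q)
  w <- pmin(abs(q[, 1L]), 1)
  as.vector(2 * acos(w) * 180 / pi)
}

#' Rotate vectors by quaternions
#'
#' Applies v' = R(q) v row-wise; either argument may have one row.
#'
#' @param q n x 4 quaternion matrix.
#' @param v n x 3 matrix of vectors (or length-3 vector).
#' @return n x 3 matrix of rotated vectors.
#' @export
quatRotate <- function(q, v) {
  q <- .asQuatMatrix(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  v <- as.matrix(v)
  if (ncol(v) != 3L) stop("vectors must have 3 components")
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1L]; u <- q[, 2:4, drop = FALSE]
  ## v' = v + 2 w (u x v) + 2 u x (u x v)
  uxv <- cbind(u[,2]*v[,3] - u[,3]*v[,2],
               u[,3]*v[,1] - u[,1]*v[,3],
               u[,1]*v[,2] - u[,2]*v[,1])
  t2 <- uxv * 2
  uxt2 <- cbind(u[,2]*t2[,3] - u[,3]*t2[,2],
                u[,3]*t2[,1] - u[,1]*t2[,3],
                u[,1]*t2[,2] - u[,2]*t2[,1])
  v + w * t2 + uxt2
}

#' Uniform random unit quaternions
#'
#' Draws rotations uniformly w.r.t. the Haar measure on SO(3) (4 i.i.d.
#' normals, normalised).
#'
#' @param n number of rotations.
#' @return n x 4 unit quaternion matrix, sign-canonical.
#' @export
randomQuat <- function(n) {
  q <- matrix(stats::rnorm(4L * n), ncol = 4L)
  quatCanonical(quatNormalize(q))
}

#' Euler angles (Bunge ZXZ, degrees) to quaternion
#'
#' The convention of CTF/ANG-style orientation files: intrinsic rotations
#' about Z by phi1, the new X by Phi, and the new Z by phi2.
#'
#' @param phi1,Phi,phi2 Euler angles in degrees (vectors recycled to a
#'   common length).
#' @return n x 4 unit quaternion matrix, sign-canonical.
#' @export
eulerToQuat <- function(phi1, Phi, phi2) {
  n <- max(length(phi1), length(Phi), length(phi2))
  phi1 <- rep_len(phi1, n); Phi <- rep_len(Phi, n); phi2 <- rep_len(phi2, n)
  if (!all(is.finite(phi1)) || !all(is.finite(Phi)) || !all(is.finite(phi2)))
    stop("Euler angles must be finite")
  h1 <- phi1 * pi / 360; h <- Phi * pi / 360; h2 <- phi2 * pi / 360
  ## qz(phi1) * qx(Phi) * qz(phi2), expanded
  c1 <- cos(h1); s1 <- sin(h1)
  cP <- cos(h);  sP <- sin(h)
  c2 <- cos(h2); s2 <- sin(h2)
  w <- c1*cP*c2 - s1*cP*s2
  x <- c1*sP*c2 + s1*sP*s2
  y <- s1*sP*c2 - c1*sP*s2
  z <- c1*cP*s2 + s1*cP*c2
  quatCanonical(cbind(w = w, x = x, y = y, z = z))
}

#' Quaternion to Euler angles (Bunge ZXZ, degrees)
#'
#' Inverse of [eulerToQuat()]. At the gimbal degeneracy Phi ~ 0 or 180 the
#' split between phi1 and phi2 is not unique; phi2 = 0 is returned there.
#'
#' @param q n x 4 unit quaternion matrix.
#' @return data.frame with columns phi1, Phi, phi2 (degrees, phi1/phi2 in
#'   [0, 360), Phi in [0, 180]).
#' @export
quatToEuler <- function(q) {
  q <- quatNormalize(.asQuatMatrix(q))
  w <- q[,1]; x <- q[,2]; y <- q[,3]; z <- q[,4]
  ## R(q) = Z(phi1) X(Phi) Z(phi2); recover from matrix elements
  r33 <- 1 - 2 * (x^2 + y^2)          # cos Phi
  Phi <- acos(pmin(pmax(r33, -1), 1))
  sP <- sin(Phi)
  deg <- 180 / pi
  phi1 <- numeric(length(w)); phi2 <- numeric(length(w))
  reg <- sP > 1e-9
  if (any(reg)) {
    r13 <- 2 * (x*z + w*y); r23 <- 2 * (y*z - w*x)    # column 3
    r31 <- 2 * (x*z - w*y); r32 <- 2 * (y*z + w*x)    # row 3
    phi1[reg] <- atan2(r13[reg], -r23[reg])
    phi2[reg] <- atan2(r31[reg], r32[reg])
  }
  if (any(!reg)) {
    ## pure rotation about Z (or 180 about an in-plane axis + Z spin)
    i <- !reg
    up <- r33[i] > 0
    ang <- 2 * atan2(z[i], w[i])
    angDown <- 2 * atan2(y[i], x[i])   # for Phi ~ 180
    phi1[i] <- ifelse(up, ang, angDown)
    phi2[i] <- 0
  }
  data.frame(phi1 = (phi1 * deg) %% 360,
             Phi = Phi * deg,
             phi2 = (phi2 * deg) %% 360)
}
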