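## Proper-rotation point groups and symmetry-aware misorientation.

#' SymmetryGroup: a finite proper-rotation point group
#'
#' Holds an ordered set of proper rotations (unit quaternions, one per row).
#' Validity requires the identity to be present, all elements distinct, and
#' closure under composition.
#'
#' @slot name character, group label (e.g. "calcite-32", "C1").
#' @slot quats numeric matrix (order x 4), sign-canonical unit quaternions.
#' @export
setClass("SymmetryGroup",
         representation(name = "character", quats = "matrix"))

setValidity("SymmetryGroup", function(object) {
  q <- object@quats
  if (ncol(q) != 4L) return("quats must have 4 columns")
  if (any(abs(sqrt(rowSums(q^2)) - 1) > 1e-9)) return("elements must be unit quaternions")
  ## identity present
  if (!any(quatAngleDeg(q) < 1e-7)) return("group must contain the identity")
  n <- nrow(q)
  ## rotation distance as |<q1, q2>| (sign-insensitive)
  same <- function(a, b) abs(tcrossprod(a, b)) > 1 - 1e-9
  eqMat <- same(q, q)
  if (any(eqMat[upper.tri(eqMat)])) return("group elements must be distinct rotations")
  for (i in seq_len(n)) {
    prod <- quatMultiply(q[i, , drop = FALSE][rep(1L, n), ], q)
    if (!all(rowSums(same(prod, q)) == 1L))
      return("group not closed under composition")
  }
  TRUE
})

setMethod("show", "SymmetryGroup", function(object) {
  cat("SymmetryGroup '", object@name, "' of order ", nrow(object@quats), "\n", sep = "")
})

#' Order of a symmetry group
#' @param sym a \linkS4class{SymmetryGroup}.
#' @return integer, number of proper rotations.
#' @export
symmetryOrder <- function(sym) nrow(sym@quats)

#' Symmetry operators as quaternions
#' @param sym a \linkS4class{SymmetryGroup}.
#' @return order x 4 quaternion matrix.
#' @export
symmetryQuats <- function(sym) sym@quats

#' The trivial point group (identity only)
#' @return a \linkS4class{SymmetryGroup} of order 1.
#' @export
trivialSymmetry <- function() {
  new("SymmetryGroup", name = "C1", quats = matrix(c(1, 0, 0, 0), nrow = 1L,
                                                   dimnames = list(NULL, c("w","x","y","z"))))
}

#' Proper rotational symmetry of calcite (point group 32)
#'
#' The six proper rotations of trigonal calcite: identity, +/-120 degrees
#' about the c-axis (crystal z), and three two-fold axes in the basal plane
#' (the a-axes, 120 degrees apart). This is the group used for
#' misorientation throughout the package.
#'
#' @return a \linkS4class{SymmetryGroup} of order 6.
#' @export
calciteSymmetry <- function() {
  q <- rbind(
    quatFromAxisAngle(c(0, 0, 1), 0),
    quatFromAxisAngle(c(0, 0, 1), 120),
    quatFromAxisAngle(c(0, 0, 1), -120),
    quatFromAxisAngle(c(1, 0, 0), 180),
    quatFromAxisAngle(c(cos(2*pi/3), sin(2*pi/3), 0), 180),
    quatFromAxisAngle(c(cos(4*pi/3), sin(4*pi/3), 0), 180))
  new("SymmetryGroup", name = "calcite-32", quats = quatCanonical(q))
}

#' Symmetry-reduced misorientation angle between orientations
#'
#' The disorientation angle: the smallest rotation angle relating the two
#' crystal orientations once the crystal symmetry is taken into account.
#' Vectorised over rows; single-row arguments are recycled.
#'
#' @param q1,q2 orientation quaternions (n x 4, or length-4 vectors).
#' @param sym a \linkS4class{SymmetryGroup} (default calcite).
#' @return numeric vector of angles in degrees, in
#'   [0, maxDisorientation(sym)].
#' @export
misorientationAngle <- function(q1, q2, sym = calciteSymmetry()) {
  q1 <- .asQuatMatrix(q1); q2 <- .asQuatMatrix(q2)
  if (nrow(q1) == 1L && nrow(q2) > 1L) q1 <- q1[rep(1L, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1L && nrow(q1) > 1L) q2 <- q2[rep(1L, nrow(q1)), , drop = FALSE]
  ## canonical argument order per row, so the function is exactly symmetric
  cmp <- sign(q1[, 1L] - q2[, 1L])
  for (k in 2:4) {
    z <- cmp == 0
    if (!any(z)) break
    cmp[z] <- sign(q1[z, k] - q2[z, k])
  }
  sw <- cmp > 0
  if (any(sw)) {
    tmp <- q1[sw, , drop = FALSE]
    q1[sw, ] <- q2[sw, , drop = FALSE]
    q2[sw, ] <- tmp
  }
  m <- quatMultiply(quatConjugate(q1), q2)
  s <- symmetryQuats(sym)
  ## |Re(m * s_k)| for each operator: rotation angle is conjugation
  ## invariant, so a single-sided sweep suffices for the angle.
  best <- abs(m[, 1L] * s[1L, 1L] - m[, 2L] * s[1L, 2L] -
              m[, 3L] * s[1L, 3L] - m[, 4L] * s[1L, 4L])
  for (k in seq_len(nrow(s))[-1L]) {
    wk <- abs(m[, 1L] * s[k, 1L] - m[, 2L] * s[k, 2L] -
              m[, 3L] * s[k, 3L] - m[, 4L] * s[k, 4L])
    best <- pmax(best, wk)
  }
  as.vector(2 * acos(pmin(best, 1)) * 180 / pi)
}

#' Maximum disorientation angle of a symmetry group
#'
#' Supremum of the symmetry-reduced misorientation angle over all
#' orientation pairs; the natural upper bound of misorientation histogram
#' axes. Computed by dense random sampling followed by local refinement
#' from the best sample, and cached per group name.
#'
#' @param sym a \linkS4class{SymmetryGroup}.
#' @param nSamples number of random orientations scanned.
#' @return angle in degrees.
#' @export
maxDisorientation <- local({
  cache <- new.env(parent = emptyenv())
  function(sym = calciteSymmetry(), nSamples = 2e5) {
    key <- sym@name
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (symmetryOrder(sym) == 1L) { cache[[key]] <- 180; return(180) }
    ## misorientation to the identity of a uniform rotation samples the
    ## full disorientation range
    q <- withr::with_seed(181L, randomQuat(nSamples))
    id <- matrix(c(1, 0, 0, 0), 1L)
    ang <- misorientationAngle(q[, , drop = FALSE], id, sym)
    q0 <- q[which.max(ang), ]
    ## refine over the rotation-vector chart around the best sample
    obj <- function(p) {
      a <- sqrt(sum(p^2))
      qq <- if (a < 1e-12) matrix(c(1, 0, 0, 0), 1L) else
        quatFromAxisAngle(p / a, a * 180 / pi)
      -misorientationAngle(qq, id, sym)
    }
    v0 <- q0[2:4]; n0 <- sqrt(sum(v0^2))
    ang0 <- 2 * atan2(n0, abs(q0[1]))
    p0 <- if (n0 < 1e-12) c(0, 0, 0) else v0 / n0 * ang0
    opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 2000))
    val <- max(max(ang), -opt$value)
    cache[[key]] <- val
    val
  }
})
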