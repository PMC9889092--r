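## OrientationMap: the raw EBSD substrate — a regular pixel grid of crystal
## orientations with an indexing mask. Map X runs along the section, map Y
## is the growth direction (inner to outer eggshell surface).

#' OrientationMap: gridded per-pixel crystal orientations
#'
#' @slot width,height map dimensions in pixels.
#' @slot stepUm pixel edge length in micrometres.
#' @slot quats (width*height) x 4 quaternion matrix, pixels in column-major
#'   order of the (height x width) grid (row = y, col = x, y = 1 at the
#'   inner surface).
#' @slot indexed logical matrix (height x width); FALSE where indexing
#'   failed (quaternion rows there are placeholders).
#' @slot frameNote free-text note on the sample frame.
#' @export
setClass("OrientationMap",
         representation(width = "integer", height = "integer",
                        stepUm = "numeric", quats = "matrix",
                        indexed = "matrix", frameNote = "character"))

setValidity("OrientationMap", function(object) {
  if (object@width < 1L || object@height < 1L) return("dims must be positive")
  if (object@stepUm <= 0) return("step must be positive")
  n <- object@width * object@height
  if (nrow(object@quats) != n || ncol(object@quats) != 4L)
    return("quats must be (width*height) x 4")
  if (!identical(dim(object@indexed), c(object@height, object@width)))
    return("indexed mask must be height x width")
  idx <- as.vector(object@indexed)
  if (any(idx & !is.finite(rowSums(object@quats))))
    return("orientation must be defined wherever indexed")
  if (any(abs(sqrt(rowSums(object@quats[idx, , drop = FALSE]^2)) - 1) > 1e-6))
    return("indexed quaternions must be unit length")
  TRUE
})

#' Construct an OrientationMap
#'
#' @param quats (width*height) x 4 quaternion matrix, column-major pixel
#'   order (y fastest).
#' @param width,height grid dimensions (pixels).
#' @param stepUm pixel size in micrometres.
#' @param indexed logical matrix (height x width) or vector; default all
#'   indexed.
#' @param frameNote sample-frame note.
#' @return an \linkS4class{OrientationMap}.
#' @export
OrientationMap <- function(quats, width, height, stepUm,
                           indexed = NULL,
                           frameNote = "map Y = growth direction (inner->outer), radial section") {
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(indexed)) indexed <- matrix(TRUE, height, width)
  if (is.null(dim(indexed))) indexed <- matrix(indexed, height, width)
  q <- .asQuatMatrix(quats)
  bad <- !as.vector(indexed)
  if (any(bad)) q[bad, ] <- rep(c(1, 0, 0, 0), each = sum(bad))
  new("OrientationMap", width = width, height = height, stepUm = stepUm,
      quats = quatCanonical(quatNormalize(q)), indexed = indexed,
      frameNote = frameNote)
}

#' @describeIn OrientationMap map width in pixels
#' @param map an OrientationMap.
#' @export
mapWidth <- function(map) map@width

#' @describeIn OrientationMap map height in pixels
#' @export
mapHeight <- function(map) map@height

#' @describeIn OrientationMap pixel size in micrometres
#' @export
mapStep <- function(map) map@stepUm

#' @describeIn OrientationMap per-pixel quaternions ((width*height) x 4)
#' @export
mapQuats <- function(map) map@quats

#' @describeIn OrientationMap logical indexing mask (height x width)
#' @export
mapIndexed <- function(map) map@indexed

setMethod("show", "OrientationMap", function(object) {
  nIdx <- sum(object@indexed)
  cat("OrientationMap ", object@width, " x ", object@height, " px @ ",
      object@stepUm, " um/px (", round(100 * nIdx / length(object@indexed), 1),
      "% indexed)\n", sep = "")
  cat("  ", object@frameNote, "\n", sep = "")
})

## linear pixel index for (y, x) in the column-major (height x width) grid
.pixIndex <- function(y, x, height) (x - 1L) * height + y

#' Per-pixel c-axis deviation from a sample direction
#'
#' Angle between each pixel's crystal c-axis and a fixed sample direction,
#' folding the c / -c equivalence into [0, 90] degrees. Eggshell calcite is
#' strongly aligned with the growth direction, so the default axis is map Y.
#'
#' @param map an \linkS4class{OrientationMap}.
#' @param axis sample-frame unit vector (default c(0, 1, 0), the growth
#'   direction).
#' @param toleranceDeg angle used for the "fraction aligned" summary.
#' @return list with \code{angles} (height x width matrix, NA where not
#'   indexed), \code{meanDeg} and \code{fracWithinTol} over indexed pixels.
#' @export
cAxisDeviation <- function(map, axis = c(0, 1, 0), toleranceDeg = 15) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-6) stop("axis must be a unit vector")
  idx <- as.vector(mapIndexed(map))
  if (!any(idx)) stop("map has no indexed pixels")
  q <- mapQuats(map)
  cSample <- cbind(2 * (q[,2]*q[,4] + q[,1]*q[,3]),
                   2 * (q[,3]*q[,4] - q[,1]*q[,2]),
                   1 - 2 * (q[,2]^2 + q[,3]^2))   # R(q) %*% (0,0,1)
  d <- abs(cSample %*% axis)
  ang <- acos(pmin(d, 1)) * 180 / pi
  ang[!idx] <- NA_real_
  angles <- matrix(ang, mapHeight(map), mapWidth(map))
  list(angles = angles,
       meanDeg = mean(ang[idx]),
       fracWithinTol = mean(ang[idx] <= toleranceDeg))
}

## Fold a set of crystal directions into the fundamental sector of the
## calcite proper group extended by the antipodal (direction) symmetry.
## With the two-fold axes along the a-axes (x and its 120-degree mates) the
## sector is: polar angle in [0, 90], azimuth in [30, 90] degrees.
.foldToSector <- function(h, sym) {
  n <- nrow(h)
  s <- symmetryQuats(sym)
  bestTheta <- rep(Inf, n); bestPhi <- rep(Inf, n)
  minTheta <- rep(Inf, n)
  for (k in seq_len(nrow(s))) {
    hk <- quatRotate(quatConjugate(s[k, , drop = FALSE]), h)
    for (sgn in c(1, -1)) {
      v <- sgn * hk
      theta <- acos(pmin(pmax(v[, 3L], -1), 1)) * 180 / pi
      phi <- (atan2(v[, 2L], v[, 1L]) * 180 / pi) %% 360
      minTheta <- pmin(minTheta, theta)
      ok <- theta <= 90 + 1e-9 & phi >= 30 - 1e-9 & phi <= 90 + 1e-9
      ## deterministic representative: smallest azimuth, then smallest polar
      upd <- ok & (phi < bestPhi - 1e-9 |
                   (abs(phi - bestPhi) <= 1e-9 & theta < bestTheta))
      bestTheta[upd] <- theta[upd]; bestPhi[upd] <- phi[upd]
    }
  }
  ## at the sector vertex (direction ~ c-axis) the azimuth is undefined and
  ## no candidate carries one inside the sector; pin it to the vertex
  deg <- !is.finite(bestPhi)
  if (any(deg)) { bestTheta[deg] <- minTheta[deg]; bestPhi[deg] <- 30 }
  cbind(theta = bestTheta, phi = bestPhi)
}

#' Inverse-pole-figure colour of orientations
#'
#' Colours an orientation by the crystal direction parallel to a chosen
#' sample direction, folded into the fundamental sector of the calcite
#' symmetry (polar 0-90, azimuth 0-60 degrees). The key is the usual
#' barycentric one: red at the c-axis vertex, green and blue at the two
#' basal vertices; the exact RGB values are a convention of this package.
#'
#' @param q orientation quaternions (n x 4).
#' @param sampleDir sample-frame unit vector being coloured (default map Y).
#' @param sym a \linkS4class{SymmetryGroup}.
#' @return n x 3 matrix of RGB values in [0, 1].
#' @export
ipfColor <- function(q, sampleDir = c(0, 1, 0), sym = calciteSymmetry()) {
  sampleDir <- as.numeric(sampleDir)
  if (abs(sqrt(sum(sampleDir^2)) - 1) > 1e-6) stop("sampleDir must be a unit vector")
  q <- .asQuatMatrix(q)
  ## crystal coordinates of the sample direction: R(q)^T d
  h <- quatRotate(quatConjugate(q), sampleDir)
  tp <- .foldToSector(h, sym)
  tFrac <- pmin(tp[, "theta"] / 90, 1)
  pFrac <- pmin(pmax((tp[, "phi"] - 30) / 60, 0), 1)
  rgb <- cbind(r = 1 - tFrac,
               g = tFrac * (1 - pFrac),
               b = tFrac * pFrac)
  ## normalise so the strongest channel saturates (standard key brightness)
  mx <- pmax(rgb[, 1L], rgb[, 2L], rgb[, 3L])
  mx[mx < 1e-12] <- 1
  rgb / mx
}
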