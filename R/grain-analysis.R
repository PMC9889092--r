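## Grain segmentation and per-grain geometry. A grain is a connected set of
## indexed pixels whose neighbouring orientations differ by less than the
## segmentation threshold; boundaries between grains are classed by the
## misorientation of the grain mean orientations.

#' GrainTable: segmented grains of an orientation map
#'
#' @slot labels integer matrix (height x width); grain id per pixel, NA
#'   where not indexed.
#' @slot meanQuats nGrains x 4 matrix of symmetry-aware mean orientations.
#' @slot info data.frame, one row per grain: grain_id, n_pixels, area_um2,
#'   centroid_x_um, centroid_y_um, semi_major_um, semi_minor_um,
#'   ellipse_theta_deg, ar, ar_flagged, n_neighbors.
#' @slot adjacency list of integer vectors: neighbouring grain ids.
#' @slot stepUm pixel size (micrometres).
#' @slot symmetry the \linkS4class{SymmetryGroup} used.
#' @slot params segmentation parameters actually applied.
#' @export
setClass("GrainTable",
         representation(labels = "matrix", meanQuats = "matrix",
                        info = "data.frame", adjacency = "list",
                        stepUm = "numeric", symmetry = "SymmetryGroup",
                        params = "list"))

setValidity("GrainTable", function(object) {
  g <- nrow(object@info)
  if (nrow(object@meanQuats) != g) return("meanQuats rows must match grains")
  if (length(object@adjacency) != g) return("adjacency length must match grains")
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > g))
    return("labels out of range")
  if (!isTRUE(all.equal(object@info$area_um2,
                        object@info$n_pixels * object@stepUm^2)))
    return("area must equal n_pixels * step^2")
  TRUE
})

setMethod("show", "GrainTable", function(object) {
  cat("GrainTable with ", nrow(object@info), " grains (",
      sum(!is.na(object@labels)), " indexed px @ ", object@stepUm,
      " um/px)\n", sep = "")
  cat("  segmentation: threshold ", object@params$thresholdDeg, " deg, ",
      object@params$connectivity, "-connected, min ", object@params$minPixels,
      " px\n", sep = "")
})

#' Number of grains
#' @param grains a \linkS4class{GrainTable}.
#' @return integer.
#' @export
nGrains <- function(grains) nrow(grains@info)

#' Per-grain summary table
#' @param grains a \linkS4class{GrainTable}.
#' @return data.frame, one row per grain.
#' @export
grainInfo <- function(grains) grains@info

#' Grain mean orientations
#' @param grains a \linkS4class{GrainTable}.
#' @return nGrains x 4 quaternion matrix.
#' @export
grainMeanQuats <- function(grains) grains@meanQuats

#' Pixel-level grain label matrix
#' @param grains a \linkS4class{GrainTable}.
#' @return integer matrix (height x width), NA where not indexed.
#' @export
grainLabels <- function(grains) grains@labels

#' Grain adjacency
#' @param grains a \linkS4class{GrainTable}.
#' @return list of integer vectors of neighbouring grain ids.
#' @export
grainAdjacency <- function(grains) grains@adjacency

## neighbour pixel pairs of a height x width grid as linear indices;
## returns a 2-column matrix. Connectivity 4 = rook, 8 = adds diagonals.
.neighbourPixelPairs <- function(height, width, connectivity) {
  y <- seq_len(height); x <- seq_len(width)
  pairs <- list()
  idx <- function(y, x) (x - 1L) * height + y
  ## right
  gx <- rep(seq_len(width - 1L), each = height); gy <- rep(y, width - 1L)
  pairs$h <- cbind(idx(gy, gx), idx(gy, gx + 1L))
  ## down
  gx <- rep(x, each = height - 1L); gy <- rep(seq_len(height - 1L), width)
  pairs$v <- cbind(idx(gy, gx), idx(gy + 1L, gx))
  if (connectivity == 8L) {
    gx <- rep(seq_len(width - 1L), each = height - 1L)
    gy <- rep(seq_len(height - 1L), width - 1L)
    pairs$d1 <- cbind(idx(gy, gx), idx(gy + 1L, gx + 1L))
    pairs$d2 <- cbind(idx(gy + 1L, gx), idx(gy, gx + 1L))
  }
  do.call(rbind, pairs)
}

#' Symmetry-aware mean orientation of a set of pixel orientations
#'
#' Projects every orientation onto the symmetry variant (and quaternion
#' sign) nearest a reference orientation (the first row by default), then
#' takes the renormalised arithmetic quaternion mean.
#'
#' @param quats n x 4 quaternion matrix.
#' @param sym a \linkS4class{SymmetryGroup}.
#' @param ref optional reference quaternion (1 x 4).
#' @return 1 x 4 unit quaternion.
#' @export
grainMeanOrientation <- function(quats, sym = calciteSymmetry(), ref = NULL) {
  q <- .asQuatMatrix(quats)
  if (nrow(q) == 0L) stop("need at least one orientation")
  if (is.null(ref)) ref <- q[1L, , drop = FALSE]
  s <- symmetryQuats(sym)
  n <- nrow(q)
  bestDot <- rep(-Inf, n)
  best <- q
  for (k in seq_len(nrow(s))) {
    qk <- quatMultiply(q, s[k, , drop = FALSE])
    d <- qk %*% t(ref)
    qk[d < 0, ] <- -qk[d < 0, , drop = FALSE]
    upd <- abs(d) > bestDot
    best[upd, ] <- qk[upd, , drop = FALSE]
    bestDot <- pmax(bestDot, abs(d))
  }
  m <- colMeans(best)
  quatCanonical(quatNormalize(matrix(m, 1L)))
}

#' Ellipse fit of a pixel set by second central moments
#'
#' The grain is approximated by the ellipse with the same second central
#' moments as the (unit-square) pixel region; for a uniform ellipse the
#' variance along a semi-axis a is a^2/4, so a = 2*sqrt(lambda1). A
#' step^2/12 term accounts for the pixel extent, which makes the moment
#' ratio of a filled axis-aligned rectangle equal its exact side ratio.
#'
#' @param ys,xs pixel coordinates (rows and columns) of the grain.
#' @param stepUm pixel size in micrometres.
#' @param arCap aspect ratio reported for degenerate (collinear) pixel sets.
#' @return list: centroid_x_um, centroid_y_um, semi_major_um, semi_minor_um,
#'   theta_deg (major-axis angle from map X, in [0, 180)), ar, flagged.
#' @export
fitEllipse <- function(ys, xs, stepUm = 1, arCap = 100) {
  n <- length(xs)
  if (n != length(ys)) stop("coordinate lengths differ")
  if (n < 1L) stop("empty pixel set")
  xu <- (xs - 0.5) * stepUm; yu <- (ys - 0.5) * stepUm
  mx <- mean(xu); my <- mean(yu)
  corr <- stepUm^2 / 12      # second moment of a single square pixel
  cxx <- mean((xu - mx)^2) + corr
  cyy <- mean((yu - my)^2) + corr
  cxy <- mean((xu - mx) * (yu - my))
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  disc <- sqrt(max((cxx - cyy)^2 / 4 + cxy^2, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  flagged <- FALSE
  if (l2 <= max(1e-12, 1e-9 * l1)) {
    flagged <- TRUE
    l2 <- max(l2, l1 / arCap^2)
  }
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  theta <- if (abs(cxy) < 1e-15 && cxx >= cyy) 0 else
    atan2(l1 - cxx, cxy) * 180 / pi
  ar <- min(a / b, arCap)
  if (ar >= arCap) flagged <- TRUE
  list(centroid_x_um = mx, centroid_y_um = my,
       semi_major_um = a, semi_minor_um = b,
       theta_deg = theta %% 180, ar = ar, flagged = flagged)
}

#' Segment an orientation map into grains
#'
#' Flood-fill partition of the indexed pixels: neighbouring pixels whose
#' misorientation is below \code{thresholdDeg} are joined into one grain
#' (connected components of the similarity graph). Grains smaller than
#' \code{minPixels} are merged into their most similar neighbouring grain
#' (or dropped when \code{mergeSmall = FALSE}). Ellipse fits, mean
#' orientations and the grain adjacency graph are computed for the final
#' partition.
#'
#' @param map an \linkS4class{OrientationMap}.
#' @param thresholdDeg segmentation threshold in degrees (default 10, the
#'   conventional grain definition).
#' @param connectivity 4 or 8 (default 8).
#' @param minPixels minimum grain size in pixels (default 5).
#' @param mergeSmall merge (default) or drop sub-threshold grains; dropped
#'   pixels lose their grain assignment.
#' @param sym a \linkS4class{SymmetryGroup}.
#' @return a \linkS4class{GrainTable}.
#' @export
segmentGrains <- function(map, thresholdDeg = 10, connectivity = 8L,
                          minPixels = 5L, mergeSmall = TRUE,
                          sym = calciteSymmetry()) {
  stopifnot(thresholdDeg > 0)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  H <- mapHeight(map); W <- mapWidth(map)
  idx <- as.vector(mapIndexed(map))
  if (!any(idx)) stop("map has no indexed pixels")
  q <- mapQuats(map)
  pairs <- .neighbourPixelPairs(H, W, connectivity)
  keep <- idx[pairs[, 1L]] & idx[pairs[, 2L]]
  pairs <- pairs[keep, , drop = FALSE]
  ang <- misorientationAngle(q[pairs[, 1L], , drop = FALSE],
                             q[pairs[, 2L], , drop = FALSE], sym)
  simil <- ang < thresholdDeg
  g <- igraph::graph_from_edgelist(pairs[simil, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, H * W - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab <- rep(NA_integer_, H * W)
  lab[idx] <- as.integer(factor(comp[idx]))
  ## ---- small-grain handling ----------------------------------------
  repeat {
    sizes <- tabulate(lab[!is.na(lab)])
    small <- which(sizes > 0L & sizes < minPixels)
    if (!length(small)) break
    ## adjacency over the *different-grain* neighbour pairs
    l1 <- lab[pairs[, 1L]]; l2 <- lab[pairs[, 2L]]
    diffp <- which(!is.na(l1) & !is.na(l2) & l1 != l2)
    if (!length(diffp)) break
    meanQ <- .grainMeans(lab, q, sym, max(lab, na.rm = TRUE))
    reassign <- rep(NA_integer_, length(sizes))
    for (s0 in small) {
      nb <- unique(c(l2[diffp][l1[diffp] == s0], l1[diffp][l2[diffp] == s0]))
      nb <- nb[sizes[nb] >= minPixels | sizes[nb] > sizes[s0]]
      if (!length(nb)) next
      a <- misorientationAngle(meanQ[rep(s0, length(nb)), , drop = FALSE],
                               meanQ[nb, , drop = FALSE], sym)
      reassign[s0] <- nb[which.min(a)]
    }
    touched <- !is.na(reassign)
    if (!any(touched)) {
      if (!mergeSmall) lab[!is.na(lab) & lab %in% small] <- NA_integer_
      break
    }
    if (mergeSmall) {
      m <- !is.na(lab) & !is.na(reassign[lab])
      lab[m] <- reassign[lab[m]]
    } else {
      lab[!is.na(lab) & lab %in% small] <- NA_integer_
      break
    }
  }
  if (all(is.na(lab))) stop("no grains left after filtering")
  lab <- as.integer(factor(lab))   # compact ids 1..G
  G <- max(lab, na.rm = TRUE)
  ## ---- per-grain statistics ----------------------------------------
  meanQ <- .grainMeans(lab, q, sym, G)
  pix <- split(which(!is.na(lab)), lab[!is.na(lab)])
  step <- mapStep(map)
  ell <- lapply(pix, function(p) {
    yy <- ((p - 1L) %% H) + 1L
    xx <- ((p - 1L) %/% H) + 1L
    fitEllipse(yy, xx, step)
  })
  nPix <- lengths(pix)
  ## adjacency of the final partition
  l1 <- lab[pairs[, 1L]]; l2 <- lab[pairs[, 2L]]
  dp <- !is.na(l1) & !is.na(l2) & l1 != l2
  adjPairs <- unique(cbind(pmin(l1[dp], l2[dp]), pmax(l1[dp], l2[dp])))
  adjacency <- rep(list(integer(0)), G)
  if (nrow(adjPairs)) {
    for (i in seq_len(G)) {
      adjacency[[i]] <- sort(unique(c(adjPairs[adjPairs[, 1L] == i, 2L],
                                      adjPairs[adjPairs[, 2L] == i, 1L])))
    }
  }
  info <- data.frame(
    grain_id = seq_len(G),
    n_pixels = as.integer(nPix),
    area_um2 = as.numeric(nPix) * step^2,
    centroid_x_um = vapply(ell, `[[`, 0, "centroid_x_um"),
    centroid_y_um = vapply(ell, `[[`, 0, "centroid_y_um"),
    semi_major_um = vapply(ell, `[[`, 0, "semi_major_um"),
    semi_minor_um = vapply(ell, `[[`, 0, "semi_minor_um"),
    ellipse_theta_deg = vapply(ell, `[[`, 0, "theta_deg"),
    ar = vapply(ell, `[[`, 0, "ar"),
    ar_flagged = vapply(ell, `[[`, TRUE, "flagged"),
    n_neighbors = lengths(adjacency),
    row.names = NULL)
  new("GrainTable",
      labels = matrix(lab, H, W), meanQuats = meanQ, info = info,
      adjacency = adjacency, stepUm = step, symmetry = sym,
      params = list(thresholdDeg = thresholdDeg, connectivity = connectivity,
                    minPixels = as.integer(minPixels), mergeSmall = mergeSmall))
}

## mean orientation per grain label
.grainMeans <- function(lab, q, sym, G) {
  out <- matrix(NA_real_, G, 4L)
  pix <- split(which(!is.na(lab)), lab[!is.na(lab)])
  for (nm in names(pix)) {
    i <- as.integer(nm)
    out[i, ] <- grainMeanOrientation(q[pix[[nm]], , drop = FALSE], sym)
  }
  out
}

#' Boundary segments between adjacent grains
#'
#' One segment per adjacent grain pair; the angle is the misorientation of
#' the two grain mean orientations. Pairs below the detection floor
#' (default 2 degrees, the usual EBSD angular-resolution convention) are
#' treated as intra-grain and excluded. Classes follow the grain-boundary
#' colour convention: low [2, 10), mid [10, 20), high >= 20 degrees.
#'
#' @param grains a \linkS4class{GrainTable}.
#' @param floorDeg detection floor in degrees.
#' @param breaks class edges, c(low/mid, mid/high).
#' @return data.frame: grain1, grain2, angle_deg, class.
#' @export
boundarySegments <- function(grains, floorDeg = 2, breaks = c(10, 20)) {
  prs <- .adjacencyPairs(grains)
  if (!nrow(prs)) {
    return(data.frame(grain1 = integer(0), grain2 = integer(0),
                      angle_deg = numeric(0),
                      class = factor(character(0), levels = c("low", "mid", "high"))))
  }
  mq <- grainMeanQuats(grains)
  ang <- misorientationAngle(mq[prs[, 1L], , drop = FALSE],
                             mq[prs[, 2L], , drop = FALSE], grains@symmetry)
  keep <- ang >= floorDeg
  cls <- cut(ang[keep], breaks = c(floorDeg, breaks, Inf),
             labels = c("low", "mid", "high"), right = FALSE)
  data.frame(grain1 = prs[keep, 1L], grain2 = prs[keep, 2L],
             angle_deg = ang[keep], class = cls)
}

## unordered adjacency pairs (i < j) of a GrainTable
.adjacencyPairs <- function(grains) {
  adj <- grainAdjacency(grains)
  if (!length(adj)) return(matrix(integer(0), 0L, 2L))
  i <- rep(seq_along(adj), lengths(adj))
  j <- unlist(adj, use.names = FALSE)
  keep <- i < j
  cbind(i[keep], j[keep])
}

#' Depth profile of low-angle boundary fraction
#'
#' Splits the map into horizontal depth bands (map Y = growth direction)
#' and reports, per band, the fraction of grain-boundary pixels whose
#' boundary class is low-angle (< 10 degrees by default classing). Bands
#' without any boundary pixels yield NA.
#'
#' @param grains a \linkS4class{GrainTable}.
#' @param segments output of [boundarySegments()] for the same grains.
#' @param nBins number of depth bands (>= 2).
#' @return data.frame: bin, y_min_um, y_max_um, n_boundary_px, frac_low.
#' @export
gbDepthProfile <- function(grains, segments, nBins = 10L) {
  if (nBins < 2L) stop("nBins must be >= 2")
  lab <- grainLabels(grains)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- .neighbourPixelPairs(H, W, 4L)   # boundary length in rook steps
  l1 <- lab[pairs[, 1L]]; l2 <- lab[pairs[, 2L]]
  dp <- which(!is.na(l1) & !is.na(l2) & l1 != l2)
  G <- nGrains(grains)
  segKey <- (pmin(segments$grain1, segments$grain2) - 1) * G +
    pmax(segments$grain1, segments$grain2)
  kp <- (pmin(l1[dp], l2[dp]) - 1) * G + pmax(l1[dp], l2[dp])
  cls <- as.character(segments$class)[match(kp, segKey)]
  keep <- !is.na(cls)               # below-floor pairs carry no boundary
  dp <- dp[keep]; cls <- cls[keep]
  y1 <- ((pairs[dp, 1L] - 1L) %% H) + 1L
  y2 <- ((pairs[dp, 2L] - 1L) %% H) + 1L
  yMid <- (y1 + y2) / 2
  yUm <- (yMid - 0.5) * grains@stepUm
  edges <- seq(0, H * grains@stepUm, length.out = nBins + 1L)
  bin <- cut(yUm, breaks = edges, include.lowest = TRUE, labels = FALSE)
  nB <- tabulate(bin, nBins)
  low <- tabulate(bin[cls == "low"], nBins)
  frac <- ifelse(nB > 0L, low / nB, NA_real_)
  data.frame(bin = seq_len(nBins),
             y_min_um = edges[-(nBins + 1L)], y_max_um = edges[-1L],
             n_boundary_px = nB, frac_low = frac)
}

#' Aspect-ratio summary with median-area filter
#'
#' Smaller grains tend to be rounder and numerically dominant, so only
#' grains with area at or above the median grain area (ties retained) enter
#' the histogram, mean and skewness; the full per-grain table is returned
#' untouched.
#'
#' @param grains a \linkS4class{GrainTable}.
#' @param binWidth histogram bin width in AR units.
#' @param filter apply the median-area filter (default TRUE).
#' @return list: meanAR, skewness, n_retained, n_total, histogram
#'   (data.frame mid/count), retained (data.frame), full (data.frame).
#' @export
arSummary <- function(grains, binWidth = 0.5, filter = TRUE) {
  info <- grainInfo(grains)
  if (nrow(info) < 2L) stop("need at least two grains")
  keep <- if (filter) info$area_um2 >= stats::median(info$area_um2) else
    rep(TRUE, nrow(info))
  if (!any(keep)) stop("all grains filtered out")
  ret <- info[keep, , drop = FALSE]
  ar <- ret$ar
  m <- mean(ar)
  s2 <- mean((ar - m)^2)
  skew <- if (s2 > 0) mean((ar - m)^3) / s2^1.5 else 0
  edges <- seq(1, max(ar) + binWidth, by = binWidth)
  hh <- graphics::hist(ar, breaks = edges, plot = FALSE)
  list(meanAR = m, skewness = skew,
       n_retained = nrow(ret), n_total = nrow(info),
       histogram = data.frame(mid = hh$mids, count = hh$counts),
       retained = ret, full = info)
}

#' Export a GrainTable as CSV
#'
#' Writes one row per grain with mean orientation as Bunge Euler angles.
#'
#' @param grains a \linkS4class{GrainTable}.
#' @param path output file.
#' @return the written data.frame, invisibly.
#' @export
writeGrainCsv <- function(grains, path) {
  eul <- quatToEuler(grainMeanQuats(grains))
  info <- grainInfo(grains)
  out <- data.frame(grain_id = info$grain_id,
                    area_um2 = info$area_um2,
                    mean_euler1 = eul$phi1, mean_euler2 = eul$Phi,
                    mean_euler3 = eul$phi2,
                    ar = info$ar,
                    ellipse_theta_deg = info$ellipse_theta_deg,
                    n_neighbors = info$n_neighbors)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
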