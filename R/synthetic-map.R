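## Synthetic eggshell orientation maps with known ground truth. A 2-D
## columnar-competition model: nucleation sites at each layer base seed
## columns that grow towards the outer surface, widen ("wedge"), tilt
## progressively ("splaying") or re-nucleate in strata ("needle"); each
## grain carries a c-axis drawn from a von Mises-Fisher distribution about
## the growth direction plus an in-plane spin about c, the lever that
## separates low-angle-dominant from high-angle-dominant neighbour-pair
## misorientation structure.

.habits <- c("wedge", "needle", "prismatic", "splaying")

#' One structural layer of a synthetic eggshell map
#'
#' @param thicknessFrac fraction of map height occupied by the layer.
#' @param nucleationPerMm nucleation sites per millimetre of map width.
#' @param habit grain habit: "wedge", "needle", "prismatic" or "splaying".
#' @param splayDegPer100Um column tilt accrued per 100 um of height
#'   (degrees; used by the splaying habit, 0 otherwise unless set).
#' @param renucleateEveryUm vertical stratum height after which columns
#'   re-nucleate (NA = the full layer; the needle habit defaults to 60 um).
#' @return a list describing the layer.
#' @export
layerSpec <- function(thicknessFrac, nucleationPerMm,
                      habit = c("prismatic", "wedge", "needle", "splaying"),
                      splayDegPer100Um = 0, renucleateEveryUm = NA) {
  habit <- match.arg(habit)
  if (habit == "needle" && is.na(renucleateEveryUm)) renucleateEveryUm <- 60
  if (habit == "splaying" && splayDegPer100Um == 0) splayDegPer100Um <- 15
  stopifnot(thicknessFrac > 0, nucleationPerMm > 0)
  list(thicknessFrac = thicknessFrac, nucleationPerMm = nucleationPerMm,
       habit = habit, splayDegPer100Um = splayDegPer100Um,
       renucleateEveryUm = renucleateEveryUm)
}

#' SyntheticSpec: recipe for a synthetic orientation map
#'
#' @slot width,height map dimensions in pixels.
#' @slot stepUm pixel size (micrometres).
#' @slot layers list of [layerSpec()] entries, inner to outer; thickness
#'   fractions must sum to 1.
#' @slot kappa von Mises-Fisher concentration of the grain c-axes about the
#'   growth direction (map Y); larger = tighter vertical alignment.
#' @slot inPlaneMode "correlated" (spins scatter around a common reference;
#'   low-angle neighbour pairs) or "uniform" (spins uniform on the circle;
#'   high-angle neighbour pairs).
#' @slot inPlaneSpreadDeg s.d. of the spin scatter in correlated mode.
#' @slot intraGradientDegPer100Um smooth intra-grain orientation drift with
#'   height (degrees per 100 um).
#' @slot dropoutFrac fraction of pixels marked non-indexed.
#' @slot seed integer seed; the map is deterministic given the spec.
#' @export
setClass("SyntheticSpec",
         representation(width = "integer", height = "integer",
                        stepUm = "numeric", layers = "list",
                        kappa = "numeric", inPlaneMode = "character",
                        inPlaneSpreadDeg = "numeric",
                        intraGradientDegPer100Um = "numeric",
                        dropoutFrac = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (!length(object@layers)) return("need at least one layer")
  fr <- vapply(object@layers, `[[`, 0, "thicknessFrac")
  if (abs(sum(fr) - 1) > 1e-6) return("layer thickness fractions must sum to 1")
  if (object@kappa <= 0) return("kappa must be positive")
  if (!object@inPlaneMode %in% c("correlated", "uniform"))
    return("inPlaneMode must be 'correlated' or 'uniform'")
  if (object@dropoutFrac < 0 || object@dropoutFrac >= 1)
    return("dropoutFrac must be in [0, 1)")
  TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec ", object@width, " x ", object@height, " px @ ",
      object@stepUm, " um/px, ", length(object@layers), " layer(s), kappa = ",
      object@kappa, ", in-plane ", object@inPlaneMode, ", seed ",
      object@seed, "\n", sep = "")
})

#' Construct a SyntheticSpec
#'
#' Defaults give a 600 x 400 px map at 2 um/px (1.2 x 0.8 mm section), the
#' scale at which the full pipeline runs in seconds.
#'
#' @param layers list of [layerSpec()] entries (inner to outer).
#' @param width,height,stepUm map geometry.
#' @param kappa c-axis vMF concentration about map Y.
#' @param inPlaneMode,inPlaneSpreadDeg in-plane spin model.
#' @param intraGradientDegPer100Um intra-grain drift.
#' @param dropoutFrac non-indexed pixel fraction.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(layers, width = 600L, height = 400L, stepUm = 2,
                          kappa = 40, inPlaneMode = c("correlated", "uniform"),
                          inPlaneSpreadDeg = 8,
                          intraGradientDegPer100Um = 1,
                          dropoutFrac = 0, seed = 1L) {
  inPlaneMode <- match.arg(inPlaneMode)
  new("SyntheticSpec", width = as.integer(width), height = as.integer(height),
      stepUm = stepUm, layers = layers, kappa = kappa,
      inPlaneMode = inPlaneMode, inPlaneSpreadDeg = inPlaneSpreadDeg,
      intraGradientDegPer100Um = intraGradientDegPer100Um,
      dropoutFrac = dropoutFrac, seed = as.integer(seed))
}

#' Morphotype presets for the synthetic generator
#'
#' Caricatures of the three palaeognath eggshell morphotypes, tuned for
#' testing the pipeline rather than reconstructing any species:
#' \describe{
#'   \item{ostrich_like}{thin wedge mammillary layer under a dominant
#'     prismatic zone of tall columns; tightly correlated in-plane spins.
#'     Expected: Type 1 neighbour-pair distribution, high aspect ratio.}
#'   \item{rhea_like}{wedge mammillary layer, splaying squamatic zone,
#'     prismatic external zone; correlated spins. Expected: Type 1,
#'     moderate aspect ratio.}
#'   \item{tinamou_like}{needle-like mammillary layer and an irregular,
#'     re-nucleating squamatic zone; uniform in-plane spins. Expected:
#'     Type 2, low aspect ratio.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed for the returned spec.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
mapPreset <- function(name = c("ostrich_like", "rhea_like", "tinamou_like"),
                      seed = 1L) {
  name <- match.arg(name)
  switch(name,
    ostrich_like = syntheticSpec(
      layers = list(
        layerSpec(0.20, 30, "wedge"),
        layerSpec(0.80, 35, "prismatic", renucleateEveryUm = 320)),
      kappa = 150, inPlaneMode = "correlated", inPlaneSpreadDeg = 5,
      intraGradientDegPer100Um = 1.5, seed = seed),
    rhea_like = syntheticSpec(
      layers = list(
        layerSpec(0.25, 35, "wedge"),
        layerSpec(0.50, 30, "splaying", splayDegPer100Um = 20,
                  renucleateEveryUm = 250),
        layerSpec(0.25, 30, "prismatic", renucleateEveryUm = 200)),
      kappa = 100, inPlaneMode = "correlated", inPlaneSpreadDeg = 6,
      intraGradientDegPer100Um = 1, seed = seed),
    tinamou_like = syntheticSpec(
      layers = list(
        layerSpec(0.35, 60, "needle"),
        layerSpec(0.65, 30, "wedge", renucleateEveryUm = 120)),
      kappa = 30, inPlaneMode = "uniform",
      intraGradientDegPer100Um = 0.5, seed = seed))
}

## sample n unit vectors from a von Mises-Fisher distribution about mu
.rvmf <- function(n, mu, kappa) {
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  th <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - w^2, 0))
  v <- cbind(s * cos(th), s * sin(th), w)       # about +Z
  ## rotate +Z onto mu
  mu <- mu / sqrt(sum(mu^2))
  if (abs(mu[3L] - 1) < 1e-12) return(v)
  if (abs(mu[3L] + 1) < 1e-12) return(cbind(v[, 1L], -v[, 2L], -v[, 3L]))
  ax <- c(-mu[2L], mu[1L], 0)
  q <- quatFromAxisAngle(ax, acos(mu[3L]) * 180 / pi)
  quatRotate(q, v)
}

## quaternion aligning the crystal c-axis (+z) with direction d, then a
## spin of phi degrees about c
.grainQuat <- function(d, phiDeg) {
  n <- nrow(d)
  z <- c(0, 0, 1)
  dot <- pmin(pmax(d[, 3L], -1), 1)
  ang <- acos(dot) * 180 / pi
  ax <- cbind(-d[, 2L], d[, 1L], 0)
  deg <- ang < 1e-9
  ax[deg, ] <- rep(c(1, 0, 0), each = sum(deg))  # any axis, angle ~ 0
  anti <- ang > 180 - 1e-9
  ax[anti, ] <- rep(c(1, 0, 0), each = sum(anti))
  qa <- quatFromAxisAngle(ax, ang)
  quatMultiply(qa, quatFromAxisAngle(z, phiDeg))
}

#' Generate a synthetic orientation map with ground truth
#'
#' Deterministic given the spec (including its seed).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{map} (an \linkS4class{OrientationMap}) and
#'   \code{truth}: \code{labels} (height x width grain ids),
#'   \code{grainQuats} (seed orientation per grain), \code{grainLayer}
#'   (layer index per grain), \code{nGrains}.
#' @export
generateMap <- function(spec) {
  methods::validObject(spec)
  W <- spec@width; H <- spec@height; step <- spec@stepUm
  withr::with_seed(spec@seed, {
    fr <- vapply(spec@layers, `[[`, 0, "thicknessFrac")
    bounds <- round(cumsum(c(0, fr)) * H)
    bounds[length(bounds)] <- H
    labels <- matrix(NA_integer_, H, W)
    grainLayer <- integer(0)
    nextId <- 0L
    widthMm <- W * step / 1000
    for (li in seq_along(spec@layers)) {
      ly <- spec@layers[[li]]
      y0 <- bounds[li] + 1L; y1 <- bounds[li + 1L]
      if (y1 < y0) next
      layH <- y1 - y0 + 1L
      strat <- if (is.na(ly$renucleateEveryUm)) layH else
        max(1L, round(ly$renucleateEveryUm / step))
      sb <- unique(c(seq(0L, layH, by = strat), layH))
      for (si in seq_len(length(sb) - 1L)) {
        r0 <- y0 + sb[si]; r1 <- y0 + sb[si + 1L] - 1L
        if (r1 < r0) next
        nNuc <- max(1L, round(ly$nucleationPerMm * widthMm))
        xNuc <- sort(stats::runif(nNuc, 0.5, W + 0.5))
        ## per-column habit parameters
        widen <- switch(ly$habit,
                        wedge = abs(stats::rnorm(nNuc, 0, 0.8)),
                        rep(0, nNuc))
        tiltDeg <- if (ly$splayDegPer100Um > 0)
          stats::rnorm(nNuc, 0, ly$splayDegPer100Um) else rep(0, nNuc)
        widthScale <- exp(stats::rnorm(nNuc, 0, switch(ly$habit,
                          wedge = 0.5, needle = 0.2, prismatic = 0.15,
                          splaying = 0.3)))
        ids <- nextId + seq_len(nNuc)
        nextId <- nextId + nNuc
        grainLayer <- c(grainLayer, rep(li, nNuc))
        xs <- seq_len(W)
        for (y in r0:r1) {
          hUm <- (y - r0 + 1L) * step
          ## progressive tilt: lateral drift of the column centreline
          drift <- tan(tiltDeg * (hUm / 100) * pi / 180) * (hUm / 2) / step
          cx <- xNuc + drift
          scale <- widthScale * (1 + widen * hUm / 100)
          d <- abs(outer(xs, cx, "-")) / rep(scale, each = W)
          labels[y, ] <- ids[max.col(-d, ties.method = "first")]
        }
      }
    }
    ## a grain is a *connected* region: weighted column competition can
    ## disconnect a column's territory, so split labels into 8-connected
    ## components and treat each component as its own grain
    pairs <- .neighbourPixelPairs(H, W, 8L)
    lv <- as.vector(labels)
    samePair <- pairs[lv[pairs[, 1L]] == lv[pairs[, 2L]], , drop = FALSE]
    gg <- igraph::graph_from_edgelist(samePair, directed = FALSE)
    gg <- igraph::add_vertices(gg, max(0L, H * W - igraph::vcount(gg)))
    comp <- igraph::components(gg)$membership
    newLab <- as.integer(factor(comp))
    parent <- vapply(split(lv, newLab), function(v) as.integer(v[1L]), 0L)
    labels <- matrix(newLab, H, W)
    G <- max(newLab)
    grainLayer <- grainLayer[parent]
    ## grain orientations (one draw per connected grain)
    cDir <- .rvmf(G, c(0, 1, 0), spec@kappa)
    phi <- if (spec@inPlaneMode == "uniform") stats::runif(G, 0, 360) else
      stats::rnorm(G, 0, spec@inPlaneSpreadDeg)
    gq <- .grainQuat(cDir, phi)
    ## per-grain intra-grain drift axis (unit, sample frame)
    dax <- matrix(stats::rnorm(3L * G), ncol = 3L)
    dax <- dax / sqrt(rowSums(dax^2))
    ## per-pixel quaternions
    lab <- as.vector(labels)
    yPix <- rep(seq_len(H), W)
    q <- gq[lab, , drop = FALSE]
    g100 <- spec@intraGradientDegPer100Um
    if (g100 > 0) {
      ## intra-grain misorientation: a smooth drift with height plus
      ## subgrain walls every ~40 um where part of the accumulated
      ## rotation localises (small-angle jumps, as in columnar calcite)
      bandUm <- 40
      nBand <- max(1L, ceiling(H * step / bandUm))
      jumps <- matrix(stats::rnorm(G * nBand, 0, g100 * bandUm / 100), G, nBand)
      cumJ <- t(apply(jumps, 1L, cumsum))
      band <- pmin(nBand, 1L + (yPix * step) %/% bandUm)
      angDrift <- g100 * (yPix * step) / 100 + cumJ[cbind(lab, band)]
      qd <- quatFromAxisAngle(dax[lab, , drop = FALSE], angDrift)
      q <- quatMultiply(qd, q)
    }
    indexed <- matrix(TRUE, H, W)
    if (spec@dropoutFrac > 0) {
      nDrop <- round(spec@dropoutFrac * H * W)
      indexed[sample.int(H * W, nDrop)] <- FALSE
    }
    map <- OrientationMap(q, W, H, step, indexed = indexed)
    truthLabels <- labels
    truthLabels[!indexed] <- NA_integer_
    list(map = map,
         truth = list(labels = truthLabels, grainQuats = gq,
                      grainLayer = grainLayer, nGrains = G))
  })
}
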