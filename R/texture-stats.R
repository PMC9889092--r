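## Misorientation distributions at the grain level: neighbour-pair (adjacent
## grains) versus random-pair sampling, and the Type 1 / Type 2 classing of
## the neighbour-pair distribution by its low-angle (< 20 degree) mass.

#' MisorientationDistribution: an angle sample with its summary
#'
#' @slot method "neighbour" or "random".
#' @slot angles numeric vector of misorientation angles (degrees).
#' @slot binWidthDeg histogram bin width (display only; the mean and the
#'   low-angle fraction are computed on the raw sample).
#' @slot nPairs number of pairs sampled.
#' @slot meanDeg sample mean (degrees).
#' @slot fracBelow20 fraction of angles below 20 degrees.
#' @slot seed integer seed used (NA for the deterministic neighbour method).
#' @export
setClass("MisorientationDistribution",
         representation(method = "character", angles = "numeric",
                        binWidthDeg = "numeric", nPairs = "integer",
                        meanDeg = "numeric", fracBelow20 = "numeric",
                        seed = "integer"))

setValidity("MisorientationDistribution", function(object) {
  if (!object@method %in% c("neighbour", "random")) return("unknown method")
  if (length(object@angles) != object@nPairs) return("nPairs must match sample")
  if (length(object@angles)) {
    if (abs(object@meanDeg - mean(object@angles)) > 1e-8)
      return("mean must be recomputable from the sample")
    if (abs(object@fracBelow20 - mean(object@angles < 20)) > 1e-12)
      return("fracBelow20 must be recomputable from the sample")
  }
  TRUE
})

setMethod("show", "MisorientationDistribution", function(object) {
  cat("MisorientationDistribution (", object@method, "-pair): n = ",
      object@nPairs, ", mean = ", round(object@meanDeg, 2),
      " deg, frac<20 = ", round(object@fracBelow20, 3), "\n", sep = "")
})

.newMD <- function(method, angles, binWidthDeg, seed = NA_integer_) {
  new("MisorientationDistribution", method = method,
      angles = as.numeric(angles), binWidthDeg = binWidthDeg,
      nPairs = length(angles), meanDeg = mean(angles),
      fracBelow20 = mean(angles < 20), seed = as.integer(seed))
}

#' Angle sample of a misorientation distribution
#' @param md a \linkS4class{MisorientationDistribution}.
#' @return numeric vector (degrees).
#' @export
mdAngles <- function(md) md@angles

#' Mean misorientation angle
#' @param md a \linkS4class{MisorientationDistribution}.
#' @return numeric (degrees).
#' @export
mdMean <- function(md) md@meanDeg

#' Fraction of misorientations below 20 degrees
#' @param md a \linkS4class{MisorientationDistribution}.
#' @return numeric in [0, 1].
#' @export
mdFracBelow20 <- function(md) md@fracBelow20

#' Histogram counts of a misorientation distribution
#' @param md a \linkS4class{MisorientationDistribution}.
#' @param sym symmetry group fixing the histogram range.
#' @return data.frame with bin mids and counts.
#' @export
mdHistogram <- function(md, sym = calciteSymmetry()) {
  top <- ceiling(maxDisorientation(sym) / md@binWidthDeg) * md@binWidthDeg
  edges <- seq(0, top, by = md@binWidthDeg)
  hh <- graphics::hist(pmin(md@angles, top - 1e-9), breaks = edges, plot = FALSE)
  data.frame(mid = hh$mids, count = hh$counts)
}

#' Neighbour-pair misorientation distribution
#'
#' One misorientation angle per unordered pair of adjacent grains, computed
#' between grain mean orientations.
#'
#' @param grains a \linkS4class{GrainTable} (with adjacency).
#' @param binWidthDeg display bin width (default 5).
#' @return a \linkS4class{MisorientationDistribution}.
#' @export
neighbourPairMD <- function(grains, binWidthDeg = 5) {
  prs <- .adjacencyPairs(grains)
  if (nrow(prs) < 1L) stop("need at least one adjacent grain pair")
  mq <- grainMeanQuats(grains)
  ang <- misorientationAngle(mq[prs[, 1L], , drop = FALSE],
                             mq[prs[, 2L], , drop = FALSE], grains@symmetry)
  .newMD("neighbour", ang, binWidthDeg)
}

#' Random-pair misorientation distribution
#'
#' Draws unordered random grain pairs (the two members of a pair are
#' distinct; grains may recur across draws, and adjacent pairs are not
#' excluded) and computes the misorientation of their mean orientations.
#'
#' @param grains a \linkS4class{GrainTable}.
#' @param nPairs number of pairs; default = number of adjacencies, for a
#'   sample size comparable with [neighbourPairMD()].
#' @param seed integer seed (mandatory: the draw is stochastic).
#' @param binWidthDeg display bin width.
#' @return a \linkS4class{MisorientationDistribution}.
#' @export
randomPairMD <- function(grains, nPairs = NULL, seed, binWidthDeg = 5) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required for random-pair sampling")
  G <- nGrains(grains)
  if (G < 2L) stop("need at least two grains")
  if (is.null(nPairs)) nPairs <- max(1L, nrow(.adjacencyPairs(grains)))
  nPairs <- as.integer(nPairs)
  if (nPairs < 1L) stop("nPairs must be >= 1")
  mq <- grainMeanQuats(grains)
  ang <- withr::with_seed(as.integer(seed), {
    i <- sample.int(G, nPairs, replace = TRUE)
    j <- sample.int(G - 1L, nPairs, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)   # j uniform on {1..G} \ {i}
    misorientationAngle(mq[i, , drop = FALSE], mq[j, , drop = FALSE],
                        grains@symmetry)
  })
  .newMD("random", ang, binWidthDeg, seed)
}

#' Classify a neighbour-pair misorientation distribution
#'
#' Operationalises the qualitative low-angle-dominant ("Type 1") versus
#' high-angle-dominant ("Type 2") distinction via the fraction of angles
#' below 20 degrees: Type1 when >= \code{type1}, weak-Type1 between
#' \code{weak} and \code{type1}, Type2 otherwise.
#'
#' @param md a \linkS4class{MisorientationDistribution} from the neighbour
#'   method.
#' @param type1,weak score thresholds (defaults 0.50 and 0.35).
#' @return list: label ("Type1", "weak-Type1" or "Type2"), score,
#'   thresholds.
#' @export
classifyMD <- function(md, type1 = 0.50, weak = 0.35) {
  if (md@method != "neighbour")
    stop("classification is defined for neighbour-pair distributions")
  if (!length(md@angles)) stop("empty angle sample")
  score <- mdFracBelow20(md)
  label <- if (score >= type1) "Type1" else if (score >= weak) "weak-Type1" else "Type2"
  list(label = label, score = score, thresholds = c(type1 = type1, weak = weak))
}

#' Export a misorientation distribution
#'
#' Writes the raw angle sample as CSV and a JSON summary.
#'
#' @param md a \linkS4class{MisorientationDistribution}.
#' @param csvPath,jsonPath output files (NULL to skip either).
#' @param class optional result of [classifyMD()] to embed in the summary.
#' @return the summary list, invisibly.
#' @export
writeMD <- function(md, csvPath = NULL, jsonPath = NULL, class = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(data.frame(angle_deg = md@angles), csvPath, row.names = FALSE)
  summ <- list(method = md@method, n = md@nPairs, mean_deg = md@meanDeg,
               frac_below_20 = md@fracBelow20)
  if (!is.null(class)) {
    summ$class <- class$label
    summ$class_thresholds <- as.list(class$thresholds)
  }
  if (!is.null(jsonPath))
    jsonlite::write_json(summ, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
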