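## Shared fixtures and independent oracles used across the test files.

## both-sided brute force over all symmetry compositions s1 * q1^-1 * q2 * s2;
## the independent oracle for the symmetry-reduced misorientation angle
bruteForceMisorientation <- function(q1, q2, sym) {
  s <- symmetryQuats(sym)
  best <- Inf
  for (i in seq_len(nrow(s))) {
    for (j in seq_len(nrow(s))) {
      m <- quatMultiply(quatMultiply(s[i, , drop = FALSE], quatConjugate(q1)),
                        quatMultiply(q2, s[j, , drop = FALSE]))
      best <- min(best, quatAngleDeg(m))
    }
  }
  best
}

## a minimal valid GrainTable from mean orientations and an adjacency list
makeGrainTable <- function(qs, adjacency = NULL, areas = NULL) {
  G <- nrow(qs)
  if (is.null(adjacency)) adjacency <- rep(list(integer(0)), G)
  if (is.null(areas)) areas <- rep(1, G)
  info <- data.frame(grain_id = seq_len(G), n_pixels = as.integer(areas),
                     area_um2 = as.numeric(areas),
                     centroid_x_um = 0, centroid_y_um = 0,
                     semi_major_um = 1, semi_minor_um = 1,
                     ellipse_theta_deg = 0, ar = 1, ar_flagged = FALSE,
                     n_neighbors = lengths(adjacency))
  lab <- rep(seq_len(G), times = as.integer(areas))
  new("GrainTable", labels = matrix(lab, 1, length(lab)), meanQuats = qs,
      info = info, adjacency = adjacency, stepUm = 1,
      symmetry = calciteSymmetry(),
      params = list(thresholdDeg = 10, connectivity = 8L, minPixels = 1L,
                    mergeSmall = TRUE))
}

## a uniform map: every pixel the same orientation
makeUniformMap <- function(q, width = 10L, height = 10L, stepUm = 1) {
  OrientationMap(matrix(rep(q, width * height), ncol = 4, byrow = TRUE),
                 width, height, stepUm)
}

## synthetic map whose grain orientations are rewritten so that adjacent
## grains differ by well-separated tilts about map X: a proper colouring of
## the ground-truth adjacency graph mapped to tilt angles. Guarantees every
## true boundary is at least minSepDeg, for segmentation-recovery tests.
makeSeparatedMap <- function(seed = 1L, width = 150L, height = 100L,
                             tilts = c(0, 25, 50, 75, 100),
                             noiseDeg = 0.3) {
  spec <- syntheticSpec(list(layerSpec(0.5, 40, "prismatic",
                                       renucleateEveryUm = 90),
                             layerSpec(0.5, 30, "prismatic",
                                       renucleateEveryUm = 80)),
                        width = width, height = height, stepUm = 2,
                        intraGradientDegPer100Um = 0, seed = seed)
  gm <- generateMap(spec)
  lab <- gm$truth$labels
  G <- gm$truth$nGrains
  ## adjacency of the truth labels (8-connected)
  H <- nrow(lab); W <- ncol(lab)
  prs <- rbind(cbind(as.vector(lab[-H, ]), as.vector(lab[-1, ])),
               cbind(as.vector(lab[, -W]), as.vector(lab[, -1])),
               cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),
               cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))
  prs <- unique(prs[prs[, 1] != prs[, 2], , drop = FALSE])
  g <- igraph::graph_from_edgelist(prs, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, G - igraph::vcount(g)))
  col <- igraph::greedy_vertex_coloring(g)
  stopifnot(max(col) <= length(tilts))
  gq <- quatFromAxisAngle(c(1, 0, 0), tilts[col])
  set.seed(seed)
  q <- gq[as.vector(lab), , drop = FALSE]
  if (noiseDeg > 0) {
    n <- nrow(q)
    ax <- matrix(rnorm(3 * n), ncol = 3)
    q <- quatMultiply(quatFromAxisAngle(ax, abs(rnorm(n, 0, noiseDeg))), q)
  }
  list(map = OrientationMap(q, W, H, 2), labels = lab, nGrains = G,
       grainQuats = gq)
}

## adjusted Rand index between two label vectors (mclust implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## random ultrametric tree with unique labels
randTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

## independent Felsenstein pruning log-likelihood for BM (used as the
## phylogenetic-independent-contrasts oracle against the dense MVN form)
picLogLik <- function(tree, x, sig2, z0) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  x <- x[tr$tip.label]
  mu <- c(x, rep(NA_real_, tr$Nnode))
  v <- c(rep(0, nTip), rep(NA_real_, tr$Nnode))
  len <- tr$edge.length
  ll <- 0
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  lastPos <- vapply(kids, max, 0L)
  for (p in as.integer(names(kids))[order(lastPos)]) {
    es <- kids[[as.character(p)]]
    ch <- tr$edge[es, 2]
    vv <- v[ch] + len[es]
    ## fold children pairwise: each fold contributes one contrast density
    m <- mu[ch[1]]; w <- vv[1]
    for (k in seq_along(ch)[-1]) {
      ll <- ll + dnorm(mu[ch[k]] - m, 0, sqrt(sig2 * (w + vv[k])), log = TRUE)
      m <- (m / w + mu[ch[k]] / vv[k]) / (1 / w + 1 / vv[k])
      w <- 1 / (1 / w + 1 / vv[k])
    }
    mu[p] <- m; v[p] <- w
  }
  root <- nTip + 1L
  unname(ll + dnorm(mu[root], z0, sqrt(sig2 * v[root]), log = TRUE))
}
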