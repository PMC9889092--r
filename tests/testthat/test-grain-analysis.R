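sym <- calciteSymmetry()

test_that("segmentation handles uniform and two-domain maps", {
  m <- makeUniformMap(c(1, 0, 0, 0))
  g <- segmentGrains(m, thresholdDeg = 10)
  expect_equal(nGrains(g), 1L)
  ## left half identity, right half 30 degrees about c
  qL <- quatFromAxisAngle(c(0, 0, 1), 0)
  qR <- quatFromAxisAngle(c(0, 0, 1), 30)
  q <- rbind(matrix(rep(qL, 50), ncol = 4, byrow = TRUE),
             matrix(rep(qR, 50), ncol = 4, byrow = TRUE))
  g2 <- segmentGrains(OrientationMap(q, 10, 10, 1), thresholdDeg = 10)
  expect_equal(nGrains(g2), 2L)
  expect_equal(grainAdjacency(g2), list(2L, 1L))
  expect_error(segmentGrains(OrientationMap(q, 10, 10, 1,
                                            indexed = matrix(FALSE, 10, 10))),
               "no indexed")
})

test_that("segmentation recovers ground truth when boundaries exceed twice the threshold", {
  fx <- makeSeparatedMap(seed = 31)
  g <- segmentGrains(fx$map, thresholdDeg = 10, minPixels = 5)
  expect_gte(ari(as.vector(grainLabels(g)), as.vector(fx$labels)), 0.95)
  ## grain count recovered within 5%
  expect_lte(abs(nGrains(g) - fx$nGrains) / fx$nGrains, 0.05)
})

test_that("the partition property holds and grain count is monotone in threshold", {
  gm <- generateMap(mapPreset("rhea_like", seed = 3))
  counts <- integer(0)
  for (th in c(3, 10, 25)) {
    g <- segmentGrains(gm$map, thresholdDeg = th)
    expect_identical(sum(grainInfo(g)$area_um2),
                     sum(mapIndexed(gm$map)) * mapStep(gm$map)^2)
    expect_identical(is.na(grainLabels(g)), !mapIndexed(gm$map))
    counts <- c(counts, nGrains(g))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("grain mean orientation is symmetry-aware and unbiased", {
  q0 <- eulerToQuat(40, 30, 70)
  expect_equal(as.vector(grainMeanOrientation(q0[rep(1, 5), ])), as.vector(q0),
               tolerance = 1e-12)
  ## two pixels at +/-2 degrees about a common axis average to the midpoint
  ax <- c(0, 1, 0)
  qa <- quatMultiply(quatFromAxisAngle(ax, 2), q0)
  qb <- quatMultiply(quatFromAxisAngle(ax, -2), q0)
  mid <- grainMeanOrientation(rbind(qa, qb))
  expect_lt(misorientationAngle(mid, q0, sym), 0.01)
  ## symmetry variants do not corrupt the mean
  s <- symmetryQuats(sym)
  qc <- quatMultiply(qa, s[2, , drop = FALSE])
  mid2 <- grainMeanOrientation(rbind(qc, qb))
  expect_lt(misorientationAngle(mid2, q0, sym), 0.01)
  ## random 3-degree intra-grain scatter: mean within 1 degree of the seed
  set.seed(32)
  axr <- matrix(rnorm(180), ncol = 3)
  qr <- quatMultiply(quatFromAxisAngle(axr, rnorm(60, 0, 3)), q0[rep(1, 60), ])
  mr <- grainMeanOrientation(qr)
  expect_lt(misorientationAngle(mr, q0, sym), 1)
})

test_that("boundary segments are classed by angle with a detection floor", {
  mk <- function(angles) {
    gq <- quatFromAxisAngle(c(1, 0, 0), c(0, angles))
    adj <- c(list(seq_along(angles) + 1L), as.list(rep(1L, length(angles))))
    makeGrainTable(gq, adjacency = adj)
  }
  seg <- boundarySegments(mk(c(5, 15, 30, 1)))
  expect_equal(nrow(seg), 3L)        # the 1-degree pair is below the floor
  expect_equal(as.character(seg$class), c("low", "mid", "high"))
  expect_equal(seg$angle_deg, c(5, 15, 30), tolerance = 1e-9)
})

test_that("boundary class proportions match a constructed mixture", {
  ## colour the truth adjacency with tilts drawn so pair differences fall in
  ## known classes: tilts 25 apart are always "high"; add a low-angle split
  fx <- makeSeparatedMap(seed = 33, noiseDeg = 0)
  g <- segmentGrains(fx$map, thresholdDeg = 10)
  seg <- boundarySegments(g)
  expect_true(all(seg$angle_deg >= 2))
  expect_true(all(as.character(seg$class) == "high"))   # separations >= 25
  expect_true(all(abs(seg$angle_deg %% 25) < 1 | abs(seg$angle_deg %% 25 - 25) < 1))
})

test_that("the depth profile localises low-angle boundaries", {
  ## three vertical thirds of 30-px columns; middle third gets 5-degree
  ## steps between columns (low), outer thirds 30-degree steps (high)
  W <- 30L; H <- 30L
  colAng <- function(x, y) {
    band <- findInterval(y, c(10.5, 20.5))  # 0, 1, 2
    if (band == 1) (x %/% 3) * 5 else (x %/% 3) * 30
  }
  q <- matrix(0, W * H, 4)
  for (x in seq_len(W)) for (y in seq_len(H))
    q[(x - 1) * H + y, ] <- quatFromAxisAngle(c(1, 0, 0), colAng(x - 1, y))
  m <- OrientationMap(q, W, H, 1)
  g <- segmentGrains(m, thresholdDeg = 4, minPixels = 1)
  seg <- boundarySegments(g)
  prof <- gbDepthProfile(g, seg, nBins = 3)
  expect_equal(nrow(prof), 3L)
  ## middle band: 90 low-angle column-boundary pixels vs 27 band-crossing
  ## high-angle pixels falling on its lower edge
  expect_true(prof$frac_low[2] > 0.7)
  expect_true(all(prof$frac_low[c(1, 3)] < 0.35))
  ## a map with no low-angle boundaries gives a zero profile
  fx <- makeSeparatedMap(seed = 34, noiseDeg = 0)
  g2 <- segmentGrains(fx$map, thresholdDeg = 10)
  prof2 <- gbDepthProfile(g2, boundarySegments(g2), nBins = 5)
  expect_true(all(prof2$frac_low == 0, na.rm = TRUE))
})

test_that("ellipse fits recover discs, rectangles, and rotated ellipses", {
  cc <- expand.grid(y = 1:41, x = 1:41)
  disc <- sqrt((cc$y - 21)^2 + (cc$x - 21)^2) <= 18
  expect_equal(fitEllipse(cc$y[disc], cc$x[disc], 1)$ar, 1, tolerance = 0.05)
  rect <- fitEllipse(rep(1:10, 40), rep(1:40, each = 10), 1)
  expect_equal(rect$ar, 4, tolerance = 0.05)
  expect_equal(rect$theta_deg, 0, tolerance = 1e-9)
  ## filled ellipse semi-axes 20 and 5, rotated 30 degrees
  th <- 30 * pi / 180
  cc <- expand.grid(y = -30:30, x = -30:30)
  xr <- cc$x * cos(th) + cc$y * sin(th)
  yr <- -cc$x * sin(th) + cc$y * cos(th)
  inside <- (xr / 20)^2 + (yr / 5)^2 <= 1
  e <- fitEllipse(cc$y[inside] + 31, cc$x[inside] + 31, 1)
  expect_equal(e$ar, 4, tolerance = 0.05 * 4)
  expect_equal(e$theta_deg, 30, tolerance = 2)
  ## a single-pixel line is a 20 x 1 rectangle under the pixel-extent
  ## moment convention
  d <- fitEllipse(rep(1, 20), 1:20, 1)
  expect_equal(d$ar, 20, tolerance = 0.05)
  ## an extreme line hits the aspect-ratio cap and is flagged
  d2 <- fitEllipse(rep(1, 400), 1:400, 1)
  expect_true(d2$flagged)
  expect_equal(d2$ar, 100)
})

test_that("ellipse fit is equivariant under a 90-degree mask rotation", {
  set.seed(35)
  ys <- sample(1:12, 200, replace = TRUE)
  xs <- sample(1:40, 200, replace = TRUE)
  e1 <- fitEllipse(ys, xs, 1)
  e2 <- fitEllipse(xs, max(ys) + 1 - ys, 1)   # rotate 90 degrees
  expect_equal(e1$ar, e2$ar, tolerance = 1e-9)
  expect_equal((e1$theta_deg + 90) %% 180, e2$theta_deg %% 180, tolerance = 1e-6)
})

test_that("the aspect-ratio summary applies the median-area filter", {
  gt <- makeGrainTable(randomQuat(4), areas = c(1, 2, 3, 4))
  gt@info$ar <- c(9, 9, 2, 3)
  s <- arSummary(gt, filter = TRUE)
  expect_equal(sort(s$retained$ar), c(2, 3))
  expect_equal(s$meanAR, 2.5)
  expect_equal(s$n_total, 4L)
  ## equal areas: everything retained
  gt2 <- makeGrainTable(randomQuat(4), areas = rep(3, 4))
  expect_equal(arSummary(gt2)$n_retained, 4L)
  ## the filter always keeps at least half the grains
  set.seed(36)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    gt3 <- makeGrainTable(randomQuat(n), areas = sample(1:10, n, replace = TRUE))
    expect_gte(arSummary(gt3)$n_retained, n / 2)
  }
  ## AR is always >= 1 on a segmented synthetic map
  g <- segmentGrains(generateMap(mapPreset("rhea_like", seed = 4))$map)
  expect_true(all(grainInfo(g)$ar >= 1))
})
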