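test_that("the generator is deterministic and honours degenerate specs", {
  spec <- syntheticSpec(list(layerSpec(1, 0.5, "prismatic")),
                        width = 40, height = 30, seed = 3)
  gm <- generateMap(spec)
  expect_equal(gm$truth$nGrains, 1L)           # one nucleation site
  expect_true(all(gm$truth$labels == 1L))
  gm2 <- generateMap(spec)
  expect_identical(mapQuats(gm$map), mapQuats(gm2$map))
  expect_identical(gm$truth$labels, gm2$truth$labels)
  ## invalid specs are rejected
  expect_error(syntheticSpec(list(layerSpec(0.5, 10, "wedge")), seed = 1),
               "sum to 1")
  expect_error(syntheticSpec(list(layerSpec(1, 10, "wedge")), kappa = -1),
               "kappa")
})

test_that("requested dropout is realised exactly and masks the truth", {
  spec <- syntheticSpec(list(layerSpec(1, 20, "prismatic")),
                        width = 100, height = 80, dropoutFrac = 0.07, seed = 5)
  gm <- generateMap(spec)
  expect_equal(mean(!mapIndexed(gm$map)), 0.07, tolerance = 0.01)
  expect_identical(is.na(gm$truth$labels), !mapIndexed(gm$map))
})

test_that("ground-truth grain count is recovered on well-separated maps", {
  fx <- makeSeparatedMap(seed = 61)
  g <- segmentGrains(fx$map, thresholdDeg = 10, minPixels = 5)
  expect_lte(abs(nGrains(g) - fx$nGrains) / fx$nGrains, 0.05)
})

test_that("morphotype presets order aspect ratio and classify as built", {
  gmO <- generateMap(mapPreset("ostrich_like", seed = 8))
  gmT <- generateMap(mapPreset("tinamou_like", seed = 8))
  gO <- segmentGrains(gmO$map)
  gT <- segmentGrains(gmT$map)
  expect_gt(arSummary(gO)$meanAR, arSummary(gT)$meanAR)
  ## strong vertical c-axis alignment in all presets
  for (p in c("ostrich_like", "rhea_like", "tinamou_like")) {
    gm <- generateMap(mapPreset(p, seed = 9))
    expect_lt(cAxisDeviation(gm$map)$meanDeg, 25)
  }
  expect_error(mapPreset("emu_like"), "arg")
})

test_that("stronger intra-grain gradients increase the low-angle boundary share", {
  ## the gradient localises into small-angle subgrain walls; segmenting at
  ## a threshold below the low/mid class edge resolves them as low-angle
  ## boundaries, so their share grows with the gradient (averaged over a
  ## fixed seed set)
  lowFrac <- function(grad, seed) {
    spec <- syntheticSpec(list(layerSpec(1, 30, "prismatic",
                                         renucleateEveryUm = 150)),
                          width = 200, height = 150, kappa = 50,
                          inPlaneMode = "uniform",
                          intraGradientDegPer100Um = grad, seed = seed)
    g <- segmentGrains(generateMap(spec)$map, thresholdDeg = 3)
    seg <- boundarySegments(g)
    mean(seg$class == "low")
  }
  m <- vapply(71:74, function(s) vapply(c(1, 4, 10), lowFrac, 0, seed = s),
              numeric(3))
  fr <- rowMeans(m)
  expect_true(all(diff(fr) > 0))
})

test_that("Brownian simulation has the right moments and reproducibility", {
  tr <- randTree(6, 80)
  expect_equal(unname(simulateBM(tr, 0, 3, seed = 1)), rep(3, 6))
  expect_identical(simulateBM(tr, 1, 0, seed = 4), simulateBM(tr, 1, 0, seed = 4))
  ## tip variance on a two-tip tree matches sig2 * t
  t2 <- ape::read.tree(text = "(A:2,B:2);")
  xs <- vapply(1:1000, function(i) simulateBM(t2, 1.3, 0, seed = 5000 + i)[1], 0)
  expect_equal(stats::var(xs), 1.3 * 2, tolerance = 0.1 * 1.3 * 2)
})

test_that("lambda simulation interpolates between BM and independence", {
  tr <- randTree(6, 81)
  expect_identical(simulateLambda(tr, 1, 1, 0, seed = 6),
                   simulateBM(tr, 1, 0, seed = 6))
  expect_error(simulateLambda(tr, 1.2, 1, 0, seed = 1), "lambda")
  ## lambda = 0 on an ultrametric tree: i.i.d. with variance sig2 * depth
  depth <- max(ape::node.depth.edgelength(tr))
  xs <- t(vapply(1:800, function(i) simulateLambda(tr, 0, 1, 0, seed = 6000 + i),
                 numeric(6)))
  cv <- stats::cov(xs)
  expect_equal(mean(diag(cv)), depth, tolerance = 0.1 * depth)
  offd <- cv[row(cv) != col(cv)]
  expect_lt(max(abs(offd)), 0.15 * depth)
  ## lambda = 0.5: empirical covariance tracks the scaled matrix
  C <- ape::vcv.phylo(tr)
  Chalf <- C * 0.5; diag(Chalf) <- diag(C)
  xs2 <- t(vapply(1:2000, function(i) simulateLambda(tr, 0.5, 1, 0, seed = 7000 + i),
                  numeric(6)))
  expect_equal(stats::cov(xs2)[lower.tri(C, diag = TRUE)],
               Chalf[lower.tri(C, diag = TRUE)],
               tolerance = 0.1 * max(C))
})
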