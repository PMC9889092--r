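test_that("BM log-likelihood agrees with the pruning (contrasts) oracle", {
  for (seed in 1:5) {
    tr <- randTree(12, seed)
    x <- simulateBM(tr, sig2 = 1.5, z0 = 3, seed = 100 + seed)
    ll <- bmLogLik(tr, x, 1.5, 3)
    expect_equal(ll, picLogLik(tr, x, 1.5, 3), tolerance = 1e-8)
  }
  ## rate/time rescaling invariance
  tr <- randTree(12, 9)
  x <- simulateBM(tr, 1, 0, seed = 1)
  tr3 <- tr; tr3$edge.length <- tr3$edge.length * 3
  expect_equal(bmLogLik(tr, x, 1.2, 0), bmLogLik(tr3, x, 0.4, 0),
               tolerance = 1e-10)
})

test_that("AICc has the right closed form and guard", {
  expect_equal(aicc(0, 2, 12), 4 + 12 / 9)
  expect_equal(aicc(-10, 3, 12), 29)
  expect_error(aicc(0, 11, 12), "n - k - 1")
})

test_that("model nesting identities hold", {
  tr <- randTree(12, 10)
  x <- simulateBM(tr, 1, 0, seed = 2)
  bm <- fitEvoModel(tr, x, "BM")
  expect_lt(abs(fitEvoModel(tr, x, "Lambda", fixed = list(lambda = 1))@logLik -
                bm@logLik), 1e-6)
  expect_lt(abs(fitEvoModel(tr, x, "EB", fixed = list(r = 0))@logLik -
                bm@logLik), 1e-6)
  ## on an ultrametric tree, lambda = 0 matches white noise
  wn <- fitEvoModel(tr, x, "WhiteNoise")
  expect_lt(abs(fitEvoModel(tr, x, "Lambda", fixed = list(lambda = 0))@logLik -
                wn@logLik), 1e-6)
  ## OU approaches BM as alpha -> 0
  ou0 <- fitEvoModel(tr, x, "OU", fixed = list(alpha = 1e-9))
  expect_lt(abs(ou0@logLik - bm@logLik), 1e-5)
  ## free fits can only improve on their nested special case
  expect_gte(fitEvoModel(tr, x, "Lambda")@logLik, bm@logLik - 1e-8)
  expect_gte(fitEvoModel(tr, x, "EB")@logLik, bm@logLik - 1e-4)
})

test_that("Pagel's lambda recovers strong and absent signal", {
  nRep <- 25
  hit1 <- hit0 <- logical(nRep)
  for (i in seq_len(nRep)) {
    tr <- randTree(100, 200 + i)
    l1 <- fitPagelLambda(tr, simulateLambda(tr, 1, 1, 0, seed = 300 + i))$lambda
    l0 <- fitPagelLambda(tr, simulateLambda(tr, 0, 1, 0, seed = 400 + i))$lambda
    hit1[i] <- l1 >= 0.9
    hit0[i] <- l0 <= 0.1
  }
  expect_gte(mean(hit1), 0.9)
  expect_gte(mean(hit0), 0.9)
  ## constant traits are degenerate
  tr <- randTree(10, 1)
  expect_error(fitPagelLambda(tr, setNames(rep(1, 10), tr$tip.label)),
               "constant")
  ## cross-check the estimate against an independent implementation
  tr <- randTree(50, 77)
  x <- simulateLambda(tr, 0.6, 1, 0, seed = 55)
  ours <- fitPagelLambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ours$logLik, ref$logL, tolerance = 1e-5)
})

test_that("model selection applies the delta-AICc rule deterministically", {
  mk <- function(model, ll, k, n = 12)
    new("EvoModelFit", model = model, params = list(), logLik = ll,
        k = as.integer(k), n = as.integer(n), AICc = aicc(ll, k, n),
        converged = TRUE, notes = character(0))
  ## engineered AICc values 10 and 11.5
  a <- mk("BM", -(10 - 4 - 12 / 9) / 2, 2)
  b <- mk("OU", -(11.5 - 6 - 24 / 8) / 2, 3)
  sel <- selectModel(list(a, b))
  expect_equal(sel$best, "BM")
  expect_equal(sel$asGood, c("BM", "OU"))
  ## 10 vs 13: the second is excluded
  b2 <- mk("OU", -(13 - 6 - 24 / 8) / 2, 3)
  sel2 <- selectModel(list(a, b2))
  expect_equal(sel2$asGood, "BM")
  ## exact ties break by fixed model order (same k, same logLik)
  tieA <- mk("BM", -1, 2); tieB <- mk("WhiteNoise", -1, 2)
  expect_identical(tieA@AICc, tieB@AICc)
  expect_equal(selectModel(list(tieB, tieA))$best, "BM")
})

test_that("BM-generated data rarely prefers OU by more than the penalty", {
  ok <- logical(10)
  for (i in 1:10) {
    tr <- randTree(12, 500 + i)
    x <- simulateBM(tr, 1, 0, seed = 600 + i)
    bm <- fitEvoModel(tr, x, "BM")
    ou <- fitEvoModel(tr, x, "OU")
    ok[i] <- bm@AICc <= ou@AICc + 2
  }
  expect_gte(mean(ok), 0.8)
})

test_that("BM parameter recovery is calibrated at 12 tips", {
  nRep <- 400
  s2 <- err <- numeric(nRep)
  for (i in seq_len(nRep)) {
    tr <- randTree(12, 700)          # one fixed tree, fresh data each time
    x <- simulateBM(tr, 1, 5, seed = 800 + i)
    f <- fitEvoModel(tr, x, "BM")
    s2[i] <- f@params$sig2
    err[i] <- f@params$z0 - 5
  }
  expect_lt(abs(stats::median(s2) - 1), 0.25)
  ci <- stats::t.test(err)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("ancestral reconstruction matches the explicit GLS oracle", {
  for (seed in 1:5) {
    tr <- randTree(12, 20 + seed)
    x <- simulateBM(tr, 1, 0, seed = 900 + seed)
    a <- asrBM(tr, x)
    fit <- fitEvoModel(tr, x, "BM")
    n <- 12
    D <- ape::node.depth.edgelength(tr)
    M <- ape::mrca(tr, full = TRUE)
    Call <- matrix(D[M], nrow(M))
    Ctt <- Call[1:n, 1:n]
    Cnt <- Call[(n + 1):(2 * n - 1), 1:n, drop = FALSE]
    Cnn <- Call[(n + 1):(2 * n - 1), (n + 1):(2 * n - 1), drop = FALSE]
    Ci <- solve(Ctt); one <- rep(1, n)
    z0 <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
    est <- as.vector(z0 + Cnt %*% Ci %*% (x - z0))
    expect_equal(asrStates(a)$estimate_log, est, tolerance = 1e-8)
    ## conditional variance including root-state uncertainty
    h <- 1 - Cnt %*% Ci %*% one
    Vc <- Cnn - Cnt %*% Ci %*% t(Cnt) +
      (h %*% t(h)) / as.numeric(one %*% Ci %*% one)
    vs <- ((asrStates(a)$ci_high - asrStates(a)$estimate_log) /
             stats::qnorm(0.975))^2
    expect_equal(vs, fit@params$sig2 * diag(Vc), tolerance = 1e-8)
  }
})

test_that("two equal branches put the root at the tip midpoint", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  a <- asrBM(t2, c(A = 2, B = 6), sig2 = 1, z0 = 4)
  expect_identical(asrStates(a)$estimate_log, 4)
  expect_equal(asrStates(a)$estimate_backtransformed, exp(4))
})

test_that("reconstruction is invariant to tip order and resolves polytomies", {
  tr <- randTree(12, 26)
  x <- simulateBM(tr, 1, 0, seed = 31)
  a1 <- asrStates(asrBM(tr, x))
  a2 <- asrStates(asrBM(tr, x[sample(names(x))]))
  expect_equal(a1, a2, tolerance = 1e-12)
  ## hard polytomy: zero-length resolution leaves the likelihood invariant
  tp <- ape::read.tree(text = "((A:1,B:1,C:1):1,D:2);")
  xp <- c(A = 1, B = 2, C = 3, D = 4)
  ap <- asrStates(asrBM(tp, xp, sig2 = 1, z0 = 2))
  expect_equal(nrow(ap), 2L)
  ## polytomy node: GLS oracle on the star-within-tree
  C <- matrix(1, 3, 3) * 1; diag(C) <- 2
  C <- rbind(cbind(C, 0), 0); C[4, 4] <- 2    # tips A,B,C,D
  Cn <- rbind(rep(0, 4), c(1, 1, 1, 0))       # root, inner node
  Ci <- solve(C); one <- rep(1, 4)
  z0 <- as.numeric((one %*% Ci %*% xp) / (one %*% Ci %*% one))
  est <- as.vector(z0 + Cn %*% Ci %*% (xp - z0))
  expect_equal(ap$estimate_log, est, tolerance = 1e-8)
})

test_that("credible intervals cover simulated node states at nominal rate", {
  ## simulate tips AND internal nodes with an independent recursion, then
  ## check 95% interval coverage pooled over nodes
  tr <- randTree(12, 40)
  nTip <- 12
  simAll <- function(seed) {
    set.seed(seed)
    st <- rep(NA_real_, nTip + tr$Nnode)
    st[nTip + 1] <- 0
    pr <- ape::reorder.phylo(tr, "postorder")
    for (e in rev(seq_len(nrow(pr$edge))))
      st[pr$edge[e, 2]] <- st[pr$edge[e, 1]] +
        rnorm(1, 0, sqrt(pr$edge.length[e]))
    st
  }
  hits <- 0; tot <- 0
  for (i in 1:150) {
    st <- simAll(3000 + i)
    x <- setNames(st[1:nTip], tr$tip.label)
    a <- asrStates(asrBM(tr, x))
    truth <- st[a$node_id]
    hits <- hits + sum(a$ci_low <= truth & truth <= a$ci_high)
    tot <- tot + length(truth)
  }
  expect_gte(hits / tot, 0.90)
  expect_lte(hits / tot, 0.98)
})

test_that("tip substitution relabels without touching the topology", {
  tr <- randTree(8, 50)
  expect_identical(graftSubstituteTips(tr, c(sp1 = "sp1")), tr)
  tr2 <- graftSubstituteTips(tr, c(sp3 = "Dinornis", sp5 = "Euryapteryx"))
  expect_identical(tr2$edge, tr$edge)
  expect_identical(tr2$edge.length, tr$edge.length)
  expect_setequal(setdiff(tr2$tip.label, tr$tip.label),
                  c("Dinornis", "Euryapteryx"))
  expect_error(graftSubstituteTips(tr, c(nope = "x")), "not in tree")
})
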