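## Evolutionary-model fitting on calibrated trees. All six models are
## Gaussian and are fitted by profiling their single structural parameter
## (lambda, alpha or the early-burst rate) over a grid followed by
## golden-section refinement; the rate sigma^2 and the root state are
## profiled out analytically by GLS at every evaluation.

.modelOrder <- c("BM", "OU", "EB", "Trend", "Lambda", "WhiteNoise")

#' EvoModelFit: a fitted evolutionary model
#'
#' @slot model one of BM, OU, EB, Trend, Lambda, WhiteNoise.
#' @slot params named list of ML parameters (always sig2 and z0, plus the
#'   model-specific parameter).
#' @slot logLik maximised log-likelihood.
#' @slot k number of free parameters.
#' @slot n number of tips.
#' @slot AICc small-sample corrected AIC.
#' @slot converged logical; FALSE flags an optimizer failure.
#' @slot notes character notes (e.g. degeneracies).
#' @export
setClass("EvoModelFit",
         representation(model = "character", params = "list",
                        logLik = "numeric", k = "integer", n = "integer",
                        AICc = "numeric", converged = "logical",
                        notes = "character"))

setValidity("EvoModelFit", function(object) {
  if (!object@model %in% .modelOrder) return("unknown model")
  expected <- aicc(object@logLik, object@k, object@n)
  if (abs(object@AICc - expected) > 1e-8) return("AICc inconsistent with logLik/k/n")
  TRUE
})

setMethod("show", "EvoModelFit", function(object) {
  p <- unlist(object@params)
  cat("EvoModelFit [", object@model, "]  logLik = ",
      round(object@logLik, 4), ", k = ", object@k, ", AICc = ",
      round(object@AICc, 4), "\n  ", sep = "")
  cat(paste(names(p), signif(p, 6), sep = " = "), sep = ", ")
  cat("\n")
  if (!object@converged) cat("  WARNING: optimizer did not converge\n")
  if (length(object@notes) && nzchar(object@notes[1L]))
    cat("  note:", object@notes, "\n")
})

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1).
#'
#' @param logLik maximised log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tips).
#' @return numeric AICc.
#' @export
aicc <- function(logLik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0 (model too rich)")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## ---- internal GLS machinery -----------------------------------------

.checkTraits <- function(tree, traits) {
  if (is.null(names(traits))) stop("traits must be named by species")
  miss <- setdiff(tree$tip.label, names(traits))
  extra <- setdiff(names(traits), tree$tip.label)
  if (length(miss) || length(extra))
    stop("tip/trait label mismatch; missing: [",
         paste(miss, collapse = ", "), "], unmatched: [",
         paste(extra, collapse = ", "), "]")
  traits[tree$tip.label]
}

## ML GLS fit of x ~ N(X beta, sig2 * V); returns profile logLik
.glsProfile <- function(x, V, X = matrix(1, length(x), 1L)) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logDetV <- 2 * sum(log(diag(ch)))
  xi <- backsolve(ch, x, transpose = TRUE)
  Xi <- backsolve(ch, X, transpose = TRUE)
  XtX <- crossprod(Xi)
  beta <- tryCatch(solve(XtX, crossprod(Xi, xi)), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  r <- xi - Xi %*% beta
  sig2 <- sum(r^2) / n
  if (sig2 <= 0) sig2 <- .Machine$double.eps
  ll <- -n / 2 * log(2 * pi) - n / 2 * log(sig2) - logDetV / 2 - n / 2
  list(beta = drop(beta), sig2 = sig2, logLik = ll)
}

## grid + golden-section profile over one structural parameter; the
## objective may be -Inf where the covariance leaves the PD cone, so the
## refinement bracket is shrunk to the feasible region first
.profile1d <- function(f, lower, upper, nGrid = 21L, tol = 1e-10) {
  grid <- seq(lower, upper, length.out = nGrid)
  vals <- vapply(grid, f, 0)
  if (all(!is.finite(vals))) return(list(par = NA_real_, value = -Inf, ok = FALSE))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(nGrid, i + 1L)]
  ## bisect each bracket end to the feasible boundary if needed
  if (!is.finite(f(hi))) {
    good <- grid[i]; bad <- hi
    for (k in 1:40) {
      mid <- (good + bad) / 2
      if (is.finite(f(mid))) good <- mid else bad <- mid
    }
    hi <- good
  }
  if (!is.finite(f(lo))) {
    good <- grid[i]; bad <- lo
    for (k in 1:40) {
      mid <- (good + bad) / 2
      if (is.finite(f(mid))) good <- mid else bad <- mid
    }
    lo <- good
  }
  fSafe <- function(p) { v <- f(p); if (is.finite(v)) v else -1e12 }
  opt <- tryCatch(stats::optimize(fSafe, c(lo, hi), maximum = TRUE, tol = tol),
                  error = function(e) NULL)
  if (is.null(opt) || opt$objective < vals[i])
    return(list(par = grid[i], value = vals[i], ok = TRUE))
  list(par = opt$maximum, value = opt$objective, ok = TRUE)
}

## lambda-transformed covariance: off-diagonals scaled, tip depths kept
.lambdaV <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

## OU covariance (root at the optimum), sigma^2 factored out
.ouV <- function(C, alpha) {
  Tt <- diag(C)
  d <- outer(Tt, Tt, "+") - 2 * C     # patristic distances
  V <- exp(-alpha * d) * (-expm1(-2 * alpha * C)) / (2 * alpha)
  V
}

## early-burst covariance, sigma^2 factored out; r <= 0
.ebV <- function(C, r) {
  if (abs(r) < 1e-12) return(C)
  expm1(r * C) / r
}

#' Brownian-motion log-likelihood
#'
#' Multivariate-normal log density of the tip values with mean z0 and
#' covariance sig2 * C, where C[i, j] is the shared root-to-tip path length
#' of tips i and j.
#'
#' @param tree an \code{ape::phylo} tree (branch lengths in Ma).
#' @param traits named numeric vector, one value per tip.
#' @param sig2 BM rate (> 0).
#' @param z0 root state.
#' @return log-likelihood (numeric).
#' @export
bmLogLik <- function(tree, traits, sig2, z0) {
  stopifnot(sig2 > 0)
  x <- .checkTraits(tree, traits)
  C <- ape::vcv.phylo(tree)
  n <- length(x)
  ch <- tryCatch(chol(sig2 * C), error = function(e)
    stop("singular phylogenetic covariance (zero-length cherry?)"))
  r <- backsolve(ch, x - z0, transpose = TRUE)
  -n / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(r^2) / 2
}

#' Fit an evolutionary model to tip data
#'
#' Maximum-likelihood fit of one of six Gaussian trait-evolution models:
#' BM (rate sig2, root z0), OU (single optimum, root at the optimum,
#' selection alpha), EB (exponentially decaying rate, slope r <= 0), Trend
#' (BM plus linear drift mu in the mean with depth), Lambda (Pagel's
#' lambda), and WhiteNoise (i.i.d. normal, no tree). Parameter counts are
#' 2, 3, 3, 3, 3 and 2 respectively.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param traits named numeric vector of tip values.
#' @param model model name.
#' @param fixed optional named list pinning the structural parameter
#'   (\code{lambda}, \code{alpha} or \code{r}) for nesting checks; the fit
#'   keeps the full parameter count.
#' @return an \linkS4class{EvoModelFit}.
#' @export
fitEvoModel <- function(tree, traits,
                        model = c("BM", "OU", "EB", "Trend", "Lambda", "WhiteNoise"),
                        fixed = list()) {
  model <- match.arg(model)
  x <- .checkTraits(tree, traits)
  n <- length(x)
  if (stats::sd(x) < 1e-12)
    stop("trait is constant across tips; model fit is degenerate")
  C <- ape::vcv.phylo(tree)
  notes <- character(0)
  converged <- TRUE
  if (model == "BM") {
    fit <- .glsProfile(x, C)
    if (is.null(fit)) stop("singular phylogenetic covariance")
    params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]))
    ll <- fit$logLik; k <- 2L
  } else if (model == "WhiteNoise") {
    fit <- .glsProfile(x, diag(n))
    params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]))
    ll <- fit$logLik; k <- 2L
  } else if (model == "Lambda") {
    offd <- C[row(C) != col(C)]
    lamMax <- if (length(offd) && max(offd) > 0) max(diag(C)) / max(offd) else 1
    f <- function(l) { g <- .glsProfile(x, .lambdaV(C, l)); if (is.null(g)) -Inf else g$logLik }
    if (!is.null(fixed$lambda)) {
      lam <- fixed$lambda
    } else {
      ## multistart: the profile can be multimodal with a spike at the PD
      ## boundary, and lambda = 0 / 1 are the hypotheses of interest
      pr1 <- .profile1d(f, 0, min(1, lamMax))
      cand <- rbind(c(pr1$par, pr1$value), c(0, f(0)), c(min(1, lamMax), f(min(1, lamMax))))
      if (lamMax > 1) {
        pr2 <- .profile1d(f, 1, lamMax, nGrid = 11L)
        cand <- rbind(cand, c(pr2$par, pr2$value))
      }
      best <- which.max(cand[, 2L])
      lam <- cand[best, 1L]; converged <- is.finite(cand[best, 2L])
    }
    fit <- .glsProfile(x, .lambdaV(C, lam))
    params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]), lambda = lam)
    ll <- fit$logLik; k <- 3L
  } else if (model == "OU") {
    Tmax <- max(diag(C))
    f <- function(la) { g <- .glsProfile(x, .ouV(C, exp(la))); if (is.null(g)) -Inf else g$logLik }
    llBM <- .glsProfile(x, C)$logLik
    if (!is.null(fixed$alpha)) {
      alpha <- fixed$alpha
    } else {
      pr <- .profile1d(f, log(1e-4 / Tmax), log(100 / Tmax), nGrid = 31L)
      alpha <- exp(pr$par); converged <- pr$ok
      if (pr$value < llBM) { alpha <- 1e-8 / Tmax; notes <- c(notes, "alpha at BM boundary") }
    }
    fit <- .glsProfile(x, .ouV(C, alpha))
    ll <- fit$logLik
    params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]), alpha = alpha)
    k <- 3L
  } else if (model == "EB") {
    Tmax <- max(diag(C))
    rMin <- -log(1e5) / Tmax
    f <- function(r) { g <- .glsProfile(x, .ebV(C, r)); if (is.null(g)) -Inf else g$logLik }
    if (!is.null(fixed$r)) {
      r <- fixed$r
    } else {
      pr <- .profile1d(f, rMin, 0)
      r <- pr$par; converged <- pr$ok
    }
    fit <- .glsProfile(x, .ebV(C, r))
    params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]), r = r)
    ll <- fit$logLik; k <- 3L
  } else { # Trend
    depth <- diag(C)
    if (stats::sd(depth) < 1e-8 * max(depth)) {
      ## ultrametric: drift is unidentifiable; collapses to BM with mu = 0
      fit <- .glsProfile(x, C)
      params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]), mu = 0)
      notes <- c(notes, "ultrametric tree: trend slope unidentifiable, mu fixed at 0")
    } else {
      fit <- .glsProfile(x, C, X = cbind(1, depth))
      params <- list(sig2 = fit$sig2, z0 = unname(fit$beta[1L]),
                     mu = unname(fit$beta[2L]))
    }
    ll <- fit$logLik; k <- 3L
  }
  new("EvoModelFit", model = model, params = params, logLik = ll,
      k = k, n = as.integer(n), AICc = aicc(ll, k, n),
      converged = converged, notes = notes)
}

#' Pagel's lambda phylogenetic signal
#'
#' ML estimate of Pagel's lambda: internal (off-diagonal) phylogenetic
#' covariances are scaled by lambda while tip-to-root depths are preserved;
#' lambda is profiled over [0, lambda_max], the largest value keeping the
#' transformed covariance positive definite.
#'
#' @param tree an \code{ape::phylo} tree (>= 3 tips).
#' @param traits named numeric vector of tip values.
#' @return list: lambda, sig2, z0, logLik, logLik0 (lambda = 0), fit (the
#'   underlying \linkS4class{EvoModelFit}).
#' @export
fitPagelLambda <- function(tree, traits) {
  if (length(tree$tip.label) < 3L) stop("need at least 3 tips")
  fit <- fitEvoModel(tree, traits, "Lambda")
  f0 <- fitEvoModel(tree, traits, "Lambda", fixed = list(lambda = 0))
  list(lambda = fit@params$lambda, sig2 = fit@params$sig2,
       z0 = fit@params$z0, logLik = fit@logLik, logLik0 = f0@logLik,
       fit = fit)
}

#' Select among fitted models by AICc
#'
#' The best model minimises AICc; every model within \code{delta} AICc of
#' the best is reported as "as good as" the best. Ties break by the fixed
#' model order BM, OU, EB, Trend, Lambda, WhiteNoise.
#'
#' @param fits list of \linkS4class{EvoModelFit} objects.
#' @param delta AICc window (default 2).
#' @return list: best (model name), bestFit, asGood (character vector),
#'   table (data.frame sorted by AICc), bmAsGood (is BM best or as-good?).
#' @export
selectModel <- function(fits, delta = 2) {
  if (!length(fits)) stop("need at least one fit")
  tab <- data.frame(
    model = vapply(fits, function(f) f@model, ""),
    k = vapply(fits, function(f) f@k, 0L),
    logLik = vapply(fits, function(f) f@logLik, 0),
    AICc = vapply(fits, function(f) f@AICc, 0))
  ord <- order(tab$AICc, match(tab$model, .modelOrder))
  tab <- tab[ord, , drop = FALSE]
  tab$deltaAICc <- tab$AICc - tab$AICc[1L]
  rownames(tab) <- NULL
  asGood <- tab$model[tab$deltaAICc < delta]
  list(best = tab$model[1L], bestFit = fits[[ord[1L]]],
       asGood = asGood, table = tab,
       bmAsGood = "BM" %in% asGood)
}

#' Relabel tips of a calibrated tree
#'
#' Substitutes tip labels (e.g. replacing a calibrated sister species by
#' the species actually sampled) without touching topology or branch
#' lengths.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param substitutions named character vector: old label -> new label.
#' @return the relabelled tree.
#' @export
graftSubstituteTips <- function(tree, substitutions) {
  if (!length(substitutions)) return(tree)
  old <- names(substitutions)
  miss <- setdiff(old, tree$tip.label)
  if (length(miss))
    stop("tip label(s) not in tree: ", paste(miss, collapse = ", "))
  tree$tip.label[match(old, tree$tip.label)] <- unname(substitutions)
  if (anyDuplicated(tree$tip.label)) stop("substitution creates duplicate tip labels")
  tree
}
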