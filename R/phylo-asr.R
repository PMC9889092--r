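## Maximum-likelihood Brownian-motion ancestral state reconstruction.
## Estimates are the joint-ML (equivalently GLS conditional-expectation)
## node states, computed by a linear-time two-pass message-passing scheme:
## an upward (tips-to-root) pruning pass and a downward pass distributing
## the information from the rest of the tree.

#' AncestralReconstruction: ML node states under Brownian motion
#'
#' @slot states data.frame: node_id (ape numbering of the input tree),
#'   estimate_log, ci_low, ci_high (95\%, symmetric on the analysis scale)
#'   and estimate_backtransformed (exp of the estimate, for traits analysed
#'   on the natural-log scale).
#' @slot sig2,z0 the fitted BM rate and root state used.
#' @slot nTips number of tips.
#' @export
setClass("AncestralReconstruction",
         representation(states = "data.frame", sig2 = "numeric",
                        z0 = "numeric", nTips = "integer"))

setMethod("show", "AncestralReconstruction", function(object) {
  cat("AncestralReconstruction (ML BM): ", nrow(object@states),
      " internal nodes, sig2 = ", signif(object@sig2, 5),
      ", root = ", signif(object@z0, 5), "\n", sep = "")
})

#' Node state table of a reconstruction
#' @param asr an \linkS4class{AncestralReconstruction}.
#' @return data.frame of per-node estimates.
#' @export
asrStates <- function(asr) asr@states

## message passing on one rooted tree; x in tip order; returns estimates
## and unit-rate variances for nodes (nTip+1)..(nTip+nNode)
.asrMessagePassing <- function(tree, x) {
  nTip <- length(tree$tip.label)
  nNode <- tree$Nnode
  nAll <- nTip + nNode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; len <- tr$edge.length
  upMu <- numeric(nAll); upV <- numeric(nAll)
  upMu[seq_len(nTip)] <- x; upV[] <- NA_real_; upV[seq_len(nTip)] <- 0
  childOf <- split(seq_len(nrow(edge)), edge[, 1L])
  ## upward: visit each parent once its last child edge appears in
  ## postorder, so every child subtree is already summarised
  lastPos <- vapply(childOf, max, 0L)
  for (p in as.integer(names(childOf))[order(lastPos)]) {
    es <- childOf[[as.character(p)]]
    ch <- edge[es, 2L]; tt <- len[es]
    vv <- upV[ch] + tt
    if (any(vv == 0)) {
      mus <- upMu[ch][vv == 0]
      if (max(mus) - min(mus) > 1e-10)
        stop("singular covariance: zero-length branches join distinct values")
      upMu[p] <- mus[1L]; upV[p] <- 0
    } else {
      w <- 1 / vv
      upV[p] <- 1 / sum(w)
      upMu[p] <- sum(w * upMu[ch]) / sum(w)
    }
  }
  ## downward (reverse postorder: parents before children)
  downMu <- numeric(nAll); downV <- rep(Inf, nAll)
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]; k <- edge[e, 2L]; tk <- len[e]
    es <- childOf[[as.character(p)]]
    sib <- es[edge[es, 2L] != k]
    prec <- if (is.finite(downV[p])) 1 / downV[p] else 0
    musum <- if (is.finite(downV[p])) downMu[p] / downV[p] else 0
    for (s in sib) {
      vs <- upV[edge[s, 2L]] + len[s]
      if (vs == 0) { prec <- Inf; musum <- upMu[edge[s, 2L]] }
      else if (is.finite(prec)) { prec <- prec + 1 / vs; musum <- musum + upMu[edge[s, 2L]] / vs }
    }
    if (is.infinite(prec)) { downMu[k] <- musum; downV[k] <- tk }
    else if (prec == 0) { downMu[k] <- NA_real_; downV[k] <- Inf }
    else { downMu[k] <- musum / prec; downV[k] <- 1 / prec + tk }
  }
  est <- numeric(nAll); vr <- numeric(nAll)
  for (k in seq_len(nAll)) {
    if (is.infinite(downV[k])) { est[k] <- upMu[k]; vr[k] <- upV[k] }
    else if (upV[k] == 0) { est[k] <- upMu[k]; vr[k] <- 0 }
    else if (downV[k] == 0) { est[k] <- downMu[k]; vr[k] <- 0 }
    else {
      w1 <- 1 / upV[k]; w2 <- 1 / downV[k]
      est[k] <- (w1 * upMu[k] + w2 * downMu[k]) / (w1 + w2)
      vr[k] <- 1 / (w1 + w2)
    }
  }
  nodes <- (nTip + 1L):nAll
  list(estimate = est[nodes], unitVar = vr[nodes], nodes = nodes)
}

#' ML Brownian-motion ancestral state reconstruction
#'
#' Estimates internal-node states under the fitted BM model (rate and root
#' state from [fitEvoModel()] unless supplied). Polytomies are treated as
#' hard and resolved internally with zero-length branches (the likelihood
#' and the reported node states are invariant to the resolution order).
#' Confidence intervals are symmetric on the analysis (log) scale; a
#' back-transformed (exponentiated) estimate is reported alongside.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param traits named numeric vector of (log-scale) tip values.
#' @param sig2,z0 optional fixed BM parameters; fitted by ML when NULL.
#' @param backTransform function applied for the back-transformed column
#'   (default exp; use identity if the trait was not log-transformed).
#' @return an \linkS4class{AncestralReconstruction}.
#' @export
asrBM <- function(tree, traits, sig2 = NULL, z0 = NULL, backTransform = exp) {
  x <- .checkTraits(tree, traits)
  if (is.null(sig2) || is.null(z0)) {
    fit <- fitEvoModel(tree, traits, "BM")
    sig2 <- fit@params$sig2; z0 <- fit@params$z0
  }
  work <- tree
  poly <- !ape::is.binary(tree)
  if (poly) work <- ape::multi2di(tree)
  mp <- .asrMessagePassing(work, x[work$tip.label])
  est <- mp$estimate; vr <- mp$unitVar * sig2
  if (poly) {
    ## map resolved nodes back to the original nodes by descendant tip sets
    keyOf <- function(tr) {
      pp <- ape::prop.part(tr)
      vapply(pp, function(s) paste(sort(attr(pp, "labels")[s]), collapse = "|"), "")
    }
    ko <- keyOf(tree); kw <- keyOf(work)
    m <- match(ko, kw)
    est <- est[m]; vr <- vr[m]
  }
  zq <- stats::qnorm(0.975)
  nTip <- length(tree$tip.label)
  states <- data.frame(
    node_id = (nTip + 1L):(nTip + tree$Nnode),
    estimate_log = est,
    ci_low = est - zq * sqrt(vr),
    ci_high = est + zq * sqrt(vr),
    estimate_backtransformed = backTransform(est))
  new("AncestralReconstruction", states = states, sig2 = sig2, z0 = z0,
      nTips = as.integer(nTip))
}
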