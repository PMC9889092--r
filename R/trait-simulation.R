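## Trait simulation on calibrated trees: Brownian motion by branch-wise
## Gaussian increments, and Pagel's-lambda structure by running BM on the
## lambda-transformed tree (off-diagonal covariances scaled, tip depths
## preserved).

#' Simulate Brownian-motion tip values on a tree
#'
#' Recursive branch-wise Gaussian increments from the root state;
#' reproducible given the seed.
#'
#' @param tree an \code{ape::phylo} tree.
#' @param sig2 BM rate (>= 0; 0 returns z0 at every tip).
#' @param z0 root state.
#' @param seed integer seed.
#' @return named numeric vector of tip values (names = tip labels).
#' @export
simulateBM <- function(tree, sig2 = 1, z0 = 0, seed) {
  stopifnot(sig2 >= 0)
  if (missing(seed)) stop("a seed is required")
  nTip <- length(tree$tip.label)
  nAll <- nTip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge; len <- tr$edge.length
  withr::with_seed(as.integer(seed), {
    inc <- stats::rnorm(nrow(edge), 0, sqrt(sig2 * len))
    state <- rep(NA_real_, nAll)
    state[nTip + 1L] <- z0                 # root (ape convention)
    for (e in rev(seq_len(nrow(edge))))    # parents before children
      state[edge[e, 2L]] <- state[edge[e, 1L]] + inc[e]
    stats::setNames(state[seq_len(nTip)], tree$tip.label)
  })
}

## rescale a tree so that its tip covariance matches the lambda transform:
## all branches scaled by lambda, then each terminal branch stretched to
## restore the original tip depth
.lambdaTree <- function(tree, lambda) {
  depths <- ape::node.depth.edgelength(tree)
  nTip <- length(tree$tip.label)
  tr <- tree
  tr$edge.length <- tr$edge.length * lambda
  tipEdge <- match(seq_len(nTip), tr$edge[, 2L])
  tr$edge.length[tipEdge] <- tr$edge.length[tipEdge] +
    (1 - lambda) * depths[seq_len(nTip)]
  tr
}

#' Simulate tip values with Pagel's-lambda covariance structure
#'
#' Brownian motion on the lambda-transformed tree: with lambda = 1 this is
#' exactly [simulateBM()] (same seed, same draw path); with lambda = 0 on
#' an ultrametric tree the tips are i.i.d. Normal(z0, sig2 * depth).
#'
#' @param tree an \code{ape::phylo} tree.
#' @param lambda phylogenetic signal in [0, 1].
#' @param sig2 rate.
#' @param z0 root state.
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulateLambda <- function(tree, lambda, sig2 = 1, z0 = 0, seed) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  simulateBM(.lambdaTree(tree, lambda), sig2, z0, seed)
}
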