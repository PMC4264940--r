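## BIN-style clustering: single linkage at a 2.2% threshold refined by
## Markov clustering (an approximation of BOLD's server-side RESL; bit-exact
## BIN reproduction is a non-goal).

#' Single-linkage pre-clustering
#'
#' OTUs are the connected components of the graph with an edge between every
#' pair at distance below the linkage threshold (default 0.022, i.e. the
#' conventional 2.2% barcode divergence).
#'
#' @param dm A [DistanceMatrix-class].
#' @param t Linkage threshold, proportion in (0, 1).
#' @return A [Partition-class] (method `"single-linkage"`).
#' @export
singleLinkagePartition <- function(dm, t = 0.022) {
  if (!(t > 0 && t < 1)) stop("threshold must be in (0, 1)")
  m <- as.matrix(dm)
  newPartition(rownames(m), .componentsBelow(m, t), "single-linkage")
}

#' Markov clustering of a similarity graph
#'
#' Deterministic MCL: self-loops are added, columns are normalized to
#' stochastic, then expansion (matrix power) and inflation (entrywise power
#' followed by renormalization) alternate until the largest entry change
#' falls below the tolerance. Clusters are read off the attractor structure.
#' Entries below the pruning threshold are zeroed each iteration for
#' stability.
#'
#' @param sim Non-negative symmetric similarity matrix (dimnames optional).
#' @param inflation Inflation exponent r > 1 (default 2).
#' @param expansion Integer expansion power e >= 2 (default 2).
#' @param tol Convergence tolerance on the max entry change (default 1e-6).
#' @param maxIter Iteration cap (default 200).
#' @param prune Entries below this are zeroed (default 1e-12).
#' @return Integer membership vector (canonical), named when `sim` has
#'   dimnames.
#' @export
mclCluster <- function(sim, inflation = 2, expansion = 2, tol = 1e-6,
                       maxIter = 200, prune = 1e-12) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2 || expansion != round(expansion))
    stop("expansion must be an integer >= 2")
  if (any(sim < 0)) stop("similarities must be non-negative")
  if (max(abs(sim - t(sim))) > 1e-12) stop("similarity matrix must be symmetric")
  M <- sim
  diag(M) <- pmax(diag(M), 1)
  normalize <- function(A) sweep(A, 2L, pmax(colSums(A), .Machine$double.xmin),
                                 "/")
  M <- normalize(M)
  for (iter in seq_len(maxIter)) {
    Mexp <- M
    for (k in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Mnew <- normalize(Mexp^inflation)
    Mnew[Mnew < prune] <- 0
    Mnew <- normalize(Mnew)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) {
      adj <- (M > 1e-6) | t(M > 1e-6)
      diag(adj) <- TRUE
      edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
      memb <- .components(nrow(M), edges)
      names(memb) <- rownames(sim)
      return(memb)
    }
  }
  stop("MCL did not converge within ", maxIter,
       " iterations (last change ", signif(delta, 3), ")")
}

#' RESL partition: single linkage refined by Markov clustering
#'
#' Runs [singleLinkagePartition()] at threshold `t`, then refines every
#' pre-cluster of at least `minRefine` members with MCL on the similarity
#' transform `s = max(0, 1 - d/t)` (monotone in distance, zero at and beyond
#' the linkage threshold). Refinement can only split within pre-clusters, so
#' the result is always a refinement of the single-linkage partition.
#'
#' @param dm A [DistanceMatrix-class] (p-distance by convention; K2P also
#'   supported upstream).
#' @param t Linkage threshold (default 0.022).
#' @param inflation,expansion,tol,maxIter MCL controls, see [mclCluster()].
#' @param minRefine Minimum pre-cluster size passed to MCL (default 4;
#'   smaller pre-clusters are kept untouched).
#' @return A [Partition-class] (method `"resl"`).
#' @export
reslPartition <- function(dm, t = 0.022, inflation = 2, expansion = 2,
                          tol = 1e-6, maxIter = 200, minRefine = 4) {
  m <- as.matrix(dm)
  pre <- singleLinkagePartition(dm, t)
  grp <- .membershipFor(pre, rownames(m))
  out <- integer(length(grp))
  nextId <- 1L
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) >= minRefine) {
      sim <- 1 - m[idx, idx, drop = FALSE] / t
      sim[sim < 0] <- 0
      sub <- mclCluster(sim, inflation = inflation, expansion = expansion,
                        tol = tol, maxIter = maxIter)
      out[idx] <- nextId - 1L + sub
      nextId <- nextId + max(sub)
    } else {
      out[idx] <- nextId
      nextId <- nextId + 1L
    }
  }
  newPartition(rownames(m), out, "resl")
}
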