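## General mixed Yule-coalescent model on an ultrametric tree: branching
## intervals, mixed likelihood, single- and multiple-threshold fits, and the
## likelihood-ratio test. A UPGMA builder is provided so the pipeline can run
## end to end without an externally estimated chronogram.

## heights above the tips for every node (tips first, ape numbering)
.nodeHeights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth[seq_len(ape::Ntip(tree))]) - depth
  pmax(h, 0)
}

.checkUltrametric <- function(tree, relTol = 1e-6) {
  h <- .nodeHeights(tree)
  tips <- h[seq_len(ape::Ntip(tree))]
  rootH <- max(h)
  if (rootH <= 0) stop("tree has zero height")
  if (max(tips) / rootH > relTol)
    stop("tree is not ultrametric (tip height spread ",
         signif(max(tips), 4), " vs root height ", signif(rootH, 4), ")")
  invisible(h)
}

#' UPGMA ultrametric tree from a distance matrix
#'
#' Average-linkage agglomeration with node heights at half the merge
#' distance; the output satisfies the ultrametric constraint exactly and can
#' be used directly as a GMYC input when no externally estimated chronogram
#' is available.
#'
#' @param dm A [DistanceMatrix-class] over at least 2 specimens.
#' @return An ultrametric `phylo`.
#' @export
upgmaTree <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 2L) stop("UPGMA needs at least 2 specimens")
  phangorn::upgma(stats::as.dist(m))
}

## OTUs as branches crossing height T; returns list(tipOtu = integer per tip
## in tree tip order, groups = list of tip label vectors)
.otusAtThreshold <- function(tree, heights, T) {
  ntip <- ape::Ntip(tree)
  hp <- heights[tree$edge[, 1L]]
  hc <- heights[tree$edge[, 2L]]
  cross <- which(hc < T & hp >= T)
  desc <- phangorn::Descendants(tree, tree$edge[cross, 2L], "tips")
  tipOtu <- integer(ntip)
  for (j in seq_along(cross)) tipOtu[desc[[j]]] <- j
  if (any(tipOtu == 0L)) stop("threshold does not intersect all lineages")
  list(tipOtu = .canonicalGroups(tipOtu),
       groups = split(tree$tip.label, .canonicalGroups(tipOtu)))
}

## Interval structure for a tip->OTU assignment with per-OTU threshold
## heights. Every edge is classified at each inter-boundary interval as a
## diversification (species) lineage or a lineage of one within-OTU
## coalescent process. Returns list(x, event, k, N) where N is the
## intervals x OTUs matrix of coalescent lineage counts.
.gmycStructure <- function(tree, heights, tipOtu, otuT) {
  ntip <- ape::Ntip(tree)
  hp <- heights[tree$edge[, 1L]]
  hc <- heights[tree$edge[, 2L]]
  desc <- phangorn::Descendants(tree, tree$edge[, 2L], "tips")
  edgeOtu <- vapply(desc, function(tt) {
    o <- unique(tipOtu[tt])
    if (length(o) == 1L) o else 0L  # 0 = spans multiple OTUs: pure species
  }, integer(1))
  edgeT <- ifelse(edgeOtu == 0L, Inf, otuT[pmax(edgeOtu, 1L)])
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  nodeH <- heights[nodes]
  ## a node is a coalescent event of OTU j when its descendants all belong
  ## to j (such nodes always lie below j's threshold); otherwise a
  ## diversification (speciation) event
  nodeDesc <- phangorn::Descendants(tree, nodes, "tips")
  nodeOtu <- vapply(nodeDesc, function(tt) {
    o <- unique(tipOtu[tt])
    if (length(o) == 1L) o else 0L
  }, integer(1))
  specH <- nodeH[nodeOtu == 0L]  # speciation (between-OTU) node heights
  bounds <- sort(unique(c(nodeH, otuT, 0)), decreasing = TRUE)
  nInt <- length(bounds) - 1L
  nOtu <- max(tipOtu)
  x <- numeric(nInt); ev <- numeric(nInt); k <- numeric(nInt)
  N <- matrix(0, nInt, nOtu)
  for (i in seq_len(nInt)) {
    up <- bounds[i]; lo <- bounds[i + 1L]
    x[i] <- up - lo
    mid <- (up + lo) / 2
    ## count of branching events at the interval's tipward end (tied node
    ## heights in constructed trees yield simultaneous events)
    ev[i] <- if (lo > 0) sum(abs(nodeH - lo) < 1e-12) else 0
    ## diversification lineages: one at the root, plus one per speciation
    ## event above the interval; species lineages persist to the present
    ## (the lineages-through-time of the species process flattens at the
    ## OTU count below the threshold)
    k[i] <- 1 + sum(specH >= up - 1e-12)
    ## coalescent lineages: branch segments below their OTU's threshold
    crossing <- hc <= lo + 1e-12 & hp >= up - 1e-12
    coal <- which(crossing & edgeOtu > 0L & mid < edgeT)
    if (length(coal))
      N[i, ] <- tabulate(edgeOtu[coal], nbins = nOtu)
  }
  list(x = x, event = ev, k = k, N = N, bounds = bounds)
}

#' Branching intervals of a tree under a threshold
#'
#' Splits the tree at height `T` (tips at 0): nodes above `T` belong to the
#' diversification process, subtrees hanging below `T` define the per-OTU
#' coalescent processes, and OTUs are the branches crossing `T`. Intervals
#' run between consecutive event heights over the whole tree (the threshold
#' and the present are additional boundaries that do not terminate in an
#' event).
#'
#' @param tree Ultrametric `phylo` with >= 3 tips.
#' @param T Threshold height, `0 < T < root height`.
#' @return List with `x` (waiting times, root to tips), `k` (diversification
#'   lineage counts), `N` (intervals x OTUs matrix of coalescent lineage
#'   counts), `yuleK` / `coalPairs` (per-event counts entering the event
#'   log-rate terms) and `otus` (list of tip labels per OTU).
#' @export
branchingIntervals <- function(tree, T) {
  heights <- .checkUltrametric(tree)
  rootH <- max(heights)
  if (!(T > 0 && T < rootH))
    stop("threshold must lie strictly between the tips and the root height ",
         signif(rootH, 6))
  cut <- .otusAtThreshold(tree, heights, T)
  st <- .gmycStructure(tree, heights, cut$tipOtu,
                       rep(T, max(cut$tipOtu)))
  st$otus <- cut$groups
  st
}

#' Mixed Yule-coalescent log-likelihood
#'
#' The tree's branching events are a superposition of a diversification
#' (generalized Yule) process over the species lineages -- which persist
#' from their origin to the present, so with a single OTU spanning the tree
#' `k = 1` throughout and with the threshold at the tips `k` equals the
#' lineage count -- and one generalized coalescent process per OTU. The
#' per-interval total branching rate is
#' `b_i = lambda1 * k_i^p1 + lambda2 * sum_j [n_ij (n_ij - 1)]^p2`, and
#' `logL = sum_i [event_i * log(b_i) - b_i * x_i]`: intervals not ending in
#' a branching event (the threshold crossing and the final stretch to the
#' present) contribute only the survival term.
#'
#' @param intervals Result of [branchingIntervals()] (or the internal
#'   structure of a fit).
#' @param lambda1,p1 Diversification rate and scaling exponent.
#' @param lambda2,p2 Coalescent rate and scaling exponent.
#' @return The log-likelihood (finite for positive rates).
#' @export
gmycLogLik <- function(intervals, lambda1, p1, lambda2, p2) {
  if (lambda1 < 0 || lambda2 < 0 || (lambda1 == 0 && lambda2 == 0))
    stop("rates must be positive")
  pair <- intervals$N * (intervals$N - 1)
  coalSum <- if (ncol(intervals$N)) rowSums(pair^p2) else 0
  b <- lambda1 * intervals$k^p1 + lambda2 * coalSum
  lb <- ifelse(intervals$event > 0 & b > 0, log(b), 0)
  ll <- sum(intervals$event * lb) - sum(b * intervals$x)
  if (any(intervals$event > 0 & b <= 0)) return(-1e10)
  if (!is.finite(ll)) return(-1e10)
  ll
}

## maximize gmycLogLik over (lambda1, p1, lambda2, p2); fixYule drops the
## diversification parameters (used for the null single-process model)
.optimStructure <- function(st, fixYule = FALSE) {
  obj <- if (fixYule) {
    function(par) -gmycLogLik(st, 0, 1, exp(par[1L]), par[2L])
  } else {
    function(par) -gmycLogLik(st, exp(par[1L]), par[2L],
                              exp(par[3L]), par[4L])
  }
  pairSum <- if (ncol(st$N)) rowSums(st$N * (st$N - 1)) else 0
  nev <- sum(st$event)
  rate1 <- max(nev / max(sum(st$k * st$x), 1e-12), 1e-3)
  rate2 <- max(nev / max(sum(pairSum * st$x), 1e-12), 1e-3)
  starts <- if (fixYule)
    list(c(log(rate2), 1), c(0, 1))
  else
    list(c(log(rate1), 1, log(rate2), 1), c(0, 1, 0, 1),
         c(log(rate1), 0.5, log(rate2), 0.5))
  lower <- if (fixYule) c(log(1e-8), 1e-6) else c(log(1e-8), 1e-6,
                                                  log(1e-8), 1e-6)
  upper <- if (fixYule) c(log(1e8), 10) else c(log(1e8), 10, log(1e8), 10)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed to converge for the mixed likelihood")
  par <- best$par
  if (fixYule)
    list(logLik = -best$value, lambda1 = 0, p1 = 1,
         lambda2 = exp(par[1L]), p2 = par[2L])
  else
    list(logLik = -best$value, lambda1 = exp(par[1L]), p1 = par[2L],
         lambda2 = exp(par[3L]), p2 = par[4L])
}

## null model: one coalescent process spanning the whole tree
.fitNull <- function(tree, heights) {
  ntip <- ape::Ntip(tree)
  st <- .gmycStructure(tree, heights, rep(1L, ntip), max(heights))
  .optimStructure(st, fixYule = TRUE)
}

#' Likelihood-ratio test of the mixed model against the null
#'
#' `LR = 2 (logL_gmyc - logL_null)`, referred to a chi-square with 3 degrees
#' of freedom (the convention of the original GMYC software: the threshold
#' is not counted as a free parameter; configurable since chi-square
#' mixtures are also used in the literature). Significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param logLnull,logLgmyc Null and mixed-model log-likelihoods.
#' @param df Degrees of freedom (default 3).
#' @param tol Tolerance for a (numerically) negative LR before erroring.
#' @return List with `LR`, `pValue`, `significance`.
#' @export
#' @examples
#' likelihoodRatioTest(2495.37, 2539.71)$LR  # 88.68
likelihoodRatioTest <- function(logLnull, logLgmyc, df = 3, tol = 1e-4) {
  LR <- 2 * (logLgmyc - logLnull)
  if (LR < -tol)
    stop("negative likelihood ratio (", signif(LR, 4),
         "): optimizer failure upstream")
  LR <- max(LR, 0)
  p <- stats::pchisq(LR, df = df, lower.tail = FALSE)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(LR = LR, pValue = p, significance = stars)
}

## candidate thresholds: midpoints between consecutive distinct node heights
## (heights closer than 1e-9 of the root height count as ties) plus one
## below the shallowest node
.candidateThresholds <- function(heights, ntip) {
  nodeH <- sort(unique(heights[-seq_len(ntip)]), decreasing = TRUE)
  tol <- 1e-9 * max(nodeH)
  nodeH <- nodeH[c(TRUE, -diff(nodeH) > tol)]
  mids <- (nodeH[-length(nodeH)] + nodeH[-1L]) / 2
  c(mids, nodeH[length(nodeH)] / 2)
}

.gmycFitAt <- function(tree, heights, T) {
  cut <- .otusAtThreshold(tree, heights, T)
  st <- .gmycStructure(tree, heights, cut$tipOtu, rep(T, max(cut$tipOtu)))
  opt <- .optimStructure(st)
  sizes <- tabulate(cut$tipOtu)
  c(opt, list(entities = length(sizes), clusters = sum(sizes > 1L),
              tipOtu = cut$tipOtu))
}

#' Fit the single-threshold GMYC model
#'
#' Evaluates every candidate threshold (midpoints between consecutive
#' distinct node heights), maximizing the mixed likelihood over
#' `(lambda1, p1, lambda2, p2)` by bounded multi-start quasi-Newton
#' optimization at each, and returns the argmax together with the null
#' (single-process) fit and the likelihood-ratio test. Confidence sets
#' collect all candidates within 2 log-likelihood units of the optimum,
#' summarized as min-max cluster/entity counts. Haplotype-collapsed input is
#' recommended.
#'
#' @param tree Ultrametric `phylo`, >= 3 tips.
#' @return A [GmycFit-class].
#' @export
fitSingleThreshold <- function(tree) {
  if (ape::Ntip(tree) < 3L) stop("GMYC fitting needs at least 3 tips")
  heights <- .checkUltrametric(tree)
  cand <- .candidateThresholds(heights, ape::Ntip(tree))
  fits <- lapply(cand, function(T) .gmycFitAt(tree, heights, T))
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  best <- which.max(ll)
  null <- .fitNull(tree, heights)
  lrt <- likelihoodRatioTest(null$logLik, ll[best])
  ci <- which(ll >= ll[best] - 2)
  clusters <- vapply(fits, `[[`, integer(1), "clusters")
  entities <- vapply(fits, `[[`, integer(1), "entities")
  fb <- fits[[best]]
  part <- newPartition(tree$tip.label, fb$tipOtu, "gmyc")
  new("GmycFit", tree = tree,
      rates = c(lambda1 = fb$lambda1, lambda2 = fb$lambda2),
      exponents = c(p1 = fb$p1, p2 = fb$p2),
      thresholds = cand[best], logLik = ll[best], nullLogLik = null$logLik,
      LR = lrt$LR, pValue = lrt$pValue,
      clusters = fb$clusters, entities = fb$entities,
      clusterCI = range(clusters[ci]), entityCI = range(entities[ci]),
      partition = part,
      candidates = data.frame(threshold = cand, logLik = ll,
                              clusters = clusters, entities = entities),
      model = "single")
}

## candidate split heights inside one OTU's subtree
.subtreeSplitHeights <- function(tree, heights, tipOtu, j) {
  ntip <- ape::Ntip(tree)
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  desc <- phangorn::Descendants(tree, nodes, "tips")
  inside <- nodes[vapply(desc, function(tt)
    all(tipOtu[tt] == j), logical(1))]
  if (!length(inside)) return(numeric(0))
  h <- sort(unique(heights[inside]), decreasing = TRUE)
  c(if (length(h) > 1L) (h[-length(h)] + h[-1L]) / 2, h[length(h)] / 2)
}

#' Fit the multiple-threshold GMYC model
#'
#' Greedy search starting from the single-threshold optimum: at each step
#' the threshold (on a subtree) whose addition most improves the maximized
#' log-likelihood is added, until no addition improves by more than
#' `improveTol` log-likelihood units or `maxThresholds` thresholds are
#' placed. With `maxThresholds = 1` the fit equals the single-threshold fit.
#'
#' @param tree Ultrametric `phylo`, >= 3 tips.
#' @param maxThresholds Maximum number of distinct thresholds (default 5).
#' @param improveTol Minimum log-likelihood improvement to accept an
#'   additional threshold (default 2, the support-interval convention).
#' @return A [GmycFit-class] (`model = "multiple"`).
#' @export
fitMultipleThreshold <- function(tree, maxThresholds = 5, improveTol = 2) {
  single <- fitSingleThreshold(tree)
  if (maxThresholds <= 1L) {
    single@model <- "multiple"
    return(single)
  }
  heights <- .checkUltrametric(tree)
  tipOtu <- .otusAtThreshold(tree, heights, single@thresholds)$tipOtu
  otuT <- rep(single@thresholds, max(tipOtu))
  cur <- list(logLik = single@logLik,
              lambda1 = single@rates[["lambda1"]], p1 = single@exponents[["p1"]],
              lambda2 = single@rates[["lambda2"]], p2 = single@exponents[["p2"]])
  steps <- data.frame(threshold = single@thresholds, logLik = single@logLik,
                      clusters = single@clusters, entities = single@entities)
  while (length(unique(otuT)) < maxThresholds) {
    bestProp <- NULL
    for (j in seq_len(max(tipOtu))) {
      if (sum(tipOtu == j) < 2L) next
      for (Tnew in .subtreeSplitHeights(tree, heights, tipOtu, j)) {
        if (Tnew >= otuT[j]) next
        prop <- .applySplit(tree, heights, tipOtu, otuT, j, Tnew)
        st <- .gmycStructure(tree, heights, prop$tipOtu, prop$otuT)
        screen <- gmycLogLik(st, cur$lambda1, cur$p1, cur$lambda2, cur$p2)
        if (is.null(bestProp) || screen > bestProp$screen)
          bestProp <- c(prop, list(screen = screen, st = st, Tnew = Tnew))
      }
    }
    if (is.null(bestProp)) break
    opt <- .optimStructure(bestProp$st)
    if (opt$logLik - cur$logLik <= improveTol) break
    tipOtu <- bestProp$tipOtu
    otuT <- bestProp$otuT
    cur <- opt
    sizes <- tabulate(tipOtu)
    steps <- rbind(steps, data.frame(threshold = bestProp$Tnew,
                                     logLik = opt$logLik,
                                     clusters = sum(sizes > 1L),
                                     entities = length(sizes)))
  }
  lrt <- likelihoodRatioTest(single@nullLogLik, cur$logLik)
  sizes <- tabulate(tipOtu)
  new("GmycFit", tree = tree,
      rates = c(lambda1 = cur$lambda1, lambda2 = cur$lambda2),
      exponents = c(p1 = cur$p1, p2 = cur$p2),
      thresholds = sort(unique(otuT), decreasing = TRUE),
      logLik = cur$logLik, nullLogLik = single@nullLogLik,
      LR = lrt$LR, pValue = lrt$pValue,
      clusters = sum(sizes > 1L), entities = length(sizes),
      clusterCI = c(sum(sizes > 1L), sum(sizes > 1L)),
      entityCI = c(length(sizes), length(sizes)),
      partition = newPartition(tree$tip.label, tipOtu, "gmyc-multiple"),
      candidates = steps, model = "multiple")
}

## split OTU j at height Tnew: members regroup as the subtree branches
## crossing Tnew
.applySplit <- function(tree, heights, tipOtu, otuT, j, Tnew) {
  hp <- heights[tree$edge[, 1L]]
  hc <- heights[tree$edge[, 2L]]
  cross <- which(hc < Tnew & hp >= Tnew)
  desc <- phangorn::Descendants(tree, tree$edge[cross, 2L], "tips")
  newOtu <- tipOtu
  newT <- otuT
  nxt <- max(tipOtu)
  first <- TRUE
  for (e in seq_along(cross)) {
    tt <- desc[[e]]
    if (!all(tipOtu[tt] == j)) next
    if (first) {
      newT[j] <- Tnew
      first <- FALSE
    } else {
      nxt <- nxt + 1L
      newOtu[tt] <- nxt
      newT[nxt] <- Tnew
    }
  }
  canon <- .canonicalGroups(newOtu)
  # reorder thresholds to the canonical OTU numbering
  ord <- vapply(seq_len(max(canon)), function(g)
    newOtu[match(g, canon)], integer(1))
  list(tipOtu = canon, otuT = newT[ord])
}

#' Write a GMYC fit report
#'
#' One row per fitted model with cluster and entity counts (with confidence
#' ranges), null and mixed log-likelihoods, the likelihood-ratio statistic
#' with significance stars, and the fitted threshold(s).
#'
#' @param fits A [GmycFit-class] or list of them.
#' @param path Optional output TSV path.
#' @return The report data.frame, invisibly when written.
#' @export
writeGmycReport <- function(fits, path = NULL) {
  if (is(fits, "GmycFit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    stars <- likelihoodRatioTest(f@nullLogLik, f@logLik)$significance
    data.frame(
      analysis = f@model,
      clusters = f@clusters,
      clusters_CI = sprintf("%d-%d", f@clusterCI[1], f@clusterCI[2]),
      entities = f@entities,
      entities_CI = sprintf("%d-%d", f@entityCI[1], f@entityCI[2]),
      logL_null = f@nullLogLik,
      logL_gmyc = f@logLik,
      LR = f@LR,
      significance = stars,
      thresholds = paste(signif(f@thresholds, 7), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
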