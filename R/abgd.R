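## Automatic Barcode Gap Discovery: prior grid, gap inference, initial and
## recursive partitions, and the model x prior scan.

#' ABGD prior intraspecific divergence grid
#'
#' Geometric series of `nSteps` prior values from `pMin` to `pMax`
#' inclusive: `P_k = pMin * (pMax/pMin)^(k/(nSteps-1))`. The default grid of
#' 10 values over [0.001, 0.1] yields the familiar column set 0.001,
#' 0.00167, 0.00278, 0.00464, 0.00774, 0.0129, 0.0215, 0.0359, 0.0599, 0.1.
#'
#' @param pMin,pMax Prior bounds, proportions with `0 < pMin <= pMax < 1`.
#' @param nSteps Number of grid values (>= 1).
#' @return Numeric vector of priors, ascending.
#' @export
#' @examples
#' signif(abgdPriorGrid(), 3)
abgdPriorGrid <- function(pMin = 0.001, pMax = 0.1, nSteps = 10) {
  if (!(pMin > 0 && pMin <= pMax && pMax < 1))
    stop("need 0 < pMin <= pMax < 1")
  if (nSteps < 1) stop("nSteps must be >= 1")
  if (nSteps == 1) {
    if (pMin != pMax) stop("nSteps = 1 requires pMin == pMax")
    return(pMin)
  }
  pMin * (pMax / pMin)^(seq(0, nSteps - 1) / (nSteps - 1))
}

## default sliding rank window for the local slope estimate
.slopeWindow <- function(nPairs) max(3L, ceiling(0.1 * nPairs))

## gap inference on a sorted ascending distance vector; returns NULL or
## list(lower, upper, location, index)
.inferGapSorted <- function(dvec, P, X, window = NULL) {
  N <- length(dvec)
  if (N < 2L) return(NULL)
  if (max(dvec) - min(dvec) <= 0) return(NULL)
  w <- if (is.null(window)) .slopeWindow(N) else window
  below <- dvec[dvec <= P]
  limit <- if (length(below)) max(below) else 0
  for (i in seq_len(N - 1L)) {
    g <- dvec[i + 1L] - dvec[i]
    if (g <= 0) next
    if (dvec[i] < limit) next
    lo <- max(1L, i - w + 1L)
    hi <- min(N, i + w)
    slope <- (dvec[hi] - dvec[lo]) / (hi - lo)
    if (g > X * slope)
      return(list(lower = dvec[i], upper = dvec[i + 1L],
                  location = (dvec[i] + dvec[i + 1L]) / 2, index = i))
  }
  NULL
}

#' Infer the barcode gap for a prior intraspecific divergence
#'
#' Sorts the pairwise distances and scans for the first significant gap at
#' or above the prior-implied intraspecific limit. The limit is the largest
#' observed distance not exceeding the prior `P` (all distances up to it are
#' attributable to intraspecific divergence under the prior). A gap between
#' consecutive sorted distances qualifies when its width exceeds `X` times
#' the local slope, estimated over a sliding window of
#' `max(3, ceiling(0.1 * nPairs))` ranks.
#'
#' @param dm A [DistanceMatrix-class] over at least 3 specimens (the method
#'   is unreliable below 3-5 samples per species).
#' @param P Prior intraspecific divergence (proportion).
#' @param X Relative gap width (default 1.5).
#' @param window Optional slope window override (ranks).
#' @return List with `lower`, `upper` (gap edges), `location` (midpoint) and
#'   `index`, or NULL when no gap qualifies.
#' @export
abgdInferGap <- function(dm, P, X = 1.5, window = NULL) {
  if (X <= 0) stop("X must be positive")
  m <- as.matrix(dm)
  if (nrow(m) < 3L) stop("gap inference needs at least 3 specimens")
  .inferGapSorted(sort(m[upper.tri(m)]), P, X, window)
}

#' Initial ABGD partition
#'
#' Specimens are clustered as the connected components of the graph whose
#' edges join pairs with distance below the inferred gap; when no gap
#' qualifies, all specimens form a single OTU.
#'
#' @inheritParams abgdInferGap
#' @return A [Partition-class] (method `"abgd"`).
#' @export
abgdInitialPartition <- function(dm, P, X = 1.5, window = NULL) {
  m <- as.matrix(dm)
  gap <- abgdInferGap(dm, P, X, window)
  groups <- if (is.null(gap)) rep(1L, nrow(m))
            else .componentsBelow(m, gap$location)
  newPartition(rownames(m), groups, "abgd")
}

#' Recursive ABGD partition
#'
#' Applies gap inference within each group of the initial partition (on the
#' group's sub-matrix, same prior and gap width) and splits until no group
#' splits further. Groups of fewer than 3 specimens are never re-split.
#' Recursion can only refine, so the recursive OTU count is always at least
#' the initial count.
#'
#' @inheritParams abgdInferGap
#' @return A [Partition-class] (method `"abgd-recursive"`).
#' @export
abgdRecursivePartition <- function(dm, P, X = 1.5, window = NULL) {
  m <- as.matrix(dm)
  init <- abgdInitialPartition(dm, P, X, window)
  groups <- .membershipFor(init, rownames(m))
  queue <- unique(groups)
  nextId <- max(groups) + 1L
  while (length(queue)) {
    g <- queue[1L]; queue <- queue[-1L]
    idx <- which(groups == g)
    if (length(idx) < 3L) next
    sub <- m[idx, idx, drop = FALSE]
    gap <- .inferGapSorted(sort(sub[upper.tri(sub)]), P, X, window)
    if (is.null(gap)) next
    comp <- .componentsBelow(sub, gap$location)
    if (max(comp) == 1L) next
    for (k in seq_len(max(comp))[-1L]) {
      groups[idx[comp == k]] <- nextId
      queue <- c(queue, nextId)
      nextId <- nextId + 1L
    }
    queue <- c(queue, g)
  }
  newPartition(rownames(m), groups, "abgd-recursive")
}

#' Scan ABGD over distance models and the prior grid
#'
#' For each model and each prior on the grid, records the OTU counts of the
#' initial and recursive partitions in the layout of a published ABGD scan
#' table. Priors at which no barcode gap is found are recorded as count 0
#' (absence-of-partition marker); the corresponding partition (a single OTU)
#' is still retained.
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param models Character vector among `"p"`, `"JC69"`, `"K2P"`.
#' @param pMin,pMax,nSteps Prior grid (see [abgdPriorGrid()]).
#' @param X Relative gap width.
#' @param window Optional slope window override.
#' @return An [AbgdScan-class].
#' @export
abgdScan <- function(alignment, models = c("p", "JC69", "K2P"),
                     pMin = 0.001, pMax = 0.1, nSteps = 10, X = 1.5,
                     window = NULL) {
  grid <- abgdPriorGrid(pMin, pMax, nSteps)
  rows <- list()
  parts <- list()
  for (model in models) {
    dm <- pairwiseDistances(alignment, model)
    for (P in grid) {
      gap <- abgdInferGap(dm, P, X, window)
      ini <- abgdInitialPartition(dm, P, X, window)
      rec <- abgdRecursivePartition(dm, P, X, window)
      found <- !is.null(gap)
      rows[[length(rows) + 1L]] <- data.frame(
        model = distModel(dm), P = P,
        initial = if (found) nOtu(ini) else 0L,
        recursive = if (found) nOtu(rec) else 0L,
        stringsAsFactors = FALSE)
      parts[[paste(distModel(dm), signif(P, 6), "initial", sep = "|")]] <- ini
      parts[[paste(distModel(dm), signif(P, 6), "recursive", sep = "|")]] <- rec
    }
  }
  new("AbgdScan", table = do.call(rbind, rows), partitions = parts,
      params = list(grid = grid, X = X, window = window))
}

#' Render an ABGD scan as a wide table
#'
#' One row per (model, partition type), one column per prior value in
#' descending order, mirroring the layout of published ABGD result tables.
#'
#' @param scan An [AbgdScan-class].
#' @param path Optional output TSV path.
#' @return The wide data.frame, invisibly when written.
#' @export
writeAbgdScan <- function(scan, path = NULL) {
  tab <- scan@table
  grid <- sort(unique(tab$P), decreasing = TRUE)
  out <- list()
  for (model in unique(tab$model)) {
    for (type in c("initial", "recursive")) {
      counts <- tab[tab$model == model, ][match(grid,
                  tab$P[tab$model == model]), type]
      out[[paste(model, type)]] <- c(model = model, partition = type,
        stats::setNames(as.character(counts), signif(grid, 3)))
    }
  }
  wide <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  rownames(wide) <- NULL
  if (!is.null(path)) {
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(wide))
  }
  wide
}
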