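## Pairwise distances under p / JC69 / K2P with pairwise deletion, and the
## barcode-gap histogram.

## encode an alignment as an integer matrix: A=1 C=2 G=3 T=4, anything else
## (N, -, other IUPAC ambiguity codes) NA; rows = specimens
.encodeAlignment <- function(alignment) {
  chars <- strsplit(as.character(alignment@seqs), "", fixed = TRUE)
  m <- do.call(rbind, lapply(chars, function(s)
    match(s, c("A", "C", "G", "T"))))
  rownames(m) <- specimenIds(alignment)
  m
}

## per-pair site-pattern counts after pairwise deletion
.pairCounts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) return(c(n = 0L, diff = 0L, ts = 0L))
  a <- a[ok]; b <- b[ok]
  d <- a != b
  # transitions: A<->G (1,3), C<->T (2,4): partners differ by 2
  ts <- d & (abs(a - b) == 2L)
  c(n = n, diff = sum(d), ts = sum(ts))
}

#' Distance from site-pattern proportions
#'
#' Evaluates the closed-form p, JC69 or K2P distance from the proportions of
#' mismatching sites. For JC69, `d = -(3/4) log(1 - (4/3) p)`; for K2P,
#' `d = -(1/2) log(1 - 2P - Q) - (1/4) log(1 - 2Q)` where `P` and `Q` are
#' the transition and transversion proportions.
#'
#' @param p Proportion of mismatching sites (used by `p` and `JC69`).
#' @param P,Q Transition and transversion proportions (used by `K2P`).
#' @param model One of `"p"`, `"JC69"`, `"K2P"`.
#' @return The distance (proportion scale).
#' @export
#' @examples
#' modelDistance(p = 0.1, model = "JC69")            # 0.107326
#' modelDistance(P = 0.10, Q = 0.05, model = "K2P")  # 0.170181
modelDistance <- function(p = NULL, P = NULL, Q = NULL,
                          model = c("p", "JC69", "K2P")) {
  model <- match.arg(model)
  switch(model,
    p = p,
    JC69 = {
      if (p >= 0.75) stop("saturation: p-distance ", signif(p, 4),
                          " >= 3/4 under JC69")
      -0.75 * log(1 - 4 * p / 3)
    },
    K2P = {
      if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
        stop("saturation: K2P undefined for P = ", signif(P, 4),
             ", Q = ", signif(Q, 4))
      -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    })
}

#' Pairwise distance matrix
#'
#' Computes all pairwise distances under the requested model, on the
#' proportion scale. Sites where either sequence carries `N`, `-` or any
#' other ambiguity code are excluded pair by pair (pairwise deletion);
#' transitions are A<->G and C<->T, all other substitutions transversions.
#'
#' @param alignment A [BarcodeAlignment-class] with at least 2 sequences.
#' @param model `"p"`, `"JC69"` or `"K2P"` (case-insensitive).
#' @return A [DistanceMatrix-class].
#' @export
pairwiseDistances <- function(alignment, model = c("K2P", "JC69", "p")) {
  model <- match.arg(toupper(model[1L]), c("K2P", "JC69", "P"))
  if (model == "P") model <- "p"
  n <- nSpecimens(alignment)
  if (n < 2L) stop("need at least 2 sequences")
  enc <- .encodeAlignment(alignment)
  ids <- rownames(enc)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in seq.int(i + 1L, n)) {
      cnt <- .pairCounts(ai, enc[j, ])
      if (cnt[["n"]] == 0L)
        stop("zero comparable sites between ", ids[i], " and ", ids[j])
      p <- cnt[["diff"]] / cnt[["n"]]
      P <- cnt[["ts"]] / cnt[["n"]]
      Q <- p - P
      dij <- tryCatch(
        modelDistance(p = p, P = P, Q = Q, model = model),
        error = function(e)
          stop(conditionMessage(e), " (pair ", ids[i], " / ", ids[j], ")",
               call. = FALSE))
      d[i, j] <- d[j, i] <- dij
    }
  }
  new("DistanceMatrix", d = d, model = model)
}

#' Barcode-gap histogram of pairwise distances
#'
#' Bins the upper-triangle pairwise distances at a fixed bin width, keeping
#' empty bins between the minimum and maximum so that a barcode gap -- the
#' discontinuity between intraspecific and interspecific distance
#' distributions -- is visible as a run of empty bins.
#'
#' @param dm A [DistanceMatrix-class].
#' @param binWidth Bin width on the proportion scale (default 0.01).
#' @return List with `table` (data.frame `bin_low`, `bin_high`, `count`),
#'   `n` (number of pairs) and `mean` (mean pairwise distance).
#' @export
distanceHistogram <- function(dm, binWidth = 0.01) {
  if (binWidth <= 0) stop("bin width must be positive")
  v <- as.matrix(dm)[upper.tri(as.matrix(dm))]
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- ceiling(max(v) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  if (max(breaks) < max(v)) breaks <- c(breaks, max(breaks) + binWidth)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  list(table = data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1L],
                          count = counts),
       n = length(v), mean = mean(v))
}

#' Write a PHYLIP-style square distance matrix
#'
#' @param dm A [DistanceMatrix-class].
#' @param path Output path.
#' @export
writeDistPhylip <- function(dm, path) {
  m <- as.matrix(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.8f", m[i, ]), collapse = " ")), con)
  invisible(path)
}
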