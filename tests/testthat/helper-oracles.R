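# Independent oracle implementations (naive loops, no shared code with the
# package internals) plus small fixture builders.

# two partitions over the same specimens induce the same set partition?
samePartition <- function(p, q) {
  a <- otuAssignments(p)
  b <- otuAssignments(q)[names(a)]
  identical(match(a, unique(a)), match(unname(b), unique(unname(b))))
}

sameGroupingVec <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# connected components by breadth-first search over a boolean adjacency
oracleComponents <- function(adj) {
  n <- nrow(adj)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# naive re-implementation of the documented gap rule: sorted distances,
# sliding-rank-window slope, first gap wider than X * slope at or above the
# largest distance <= P
oracleGap <- function(dvec, P, X = 1.5, w = NULL) {
  dvec <- sort(dvec)
  N <- length(dvec)
  if (max(dvec) == min(dvec)) return(NULL)
  if (is.null(w)) w <- max(3, ceiling(0.1 * N))
  limit <- 0
  for (d in dvec) if (d <= P && d > limit) limit <- d
  for (i in 1:(N - 1)) {
    g <- dvec[i + 1] - dvec[i]
    if (g <= 0 || dvec[i] < limit) next
    lo <- max(1, i - w + 1)
    hi <- min(N, i + w)
    slope <- (dvec[hi] - dvec[lo]) / (hi - lo)
    if (g > X * slope) return((dvec[i] + dvec[i + 1]) / 2)
  }
  NULL
}

# exhaustive ABGD partition oracle: gap via oracleGap, clusters via BFS
oracleAbgdInitial <- function(m, P, X = 1.5) {
  gap <- oracleGap(m[upper.tri(m)], P, X)
  if (is.null(gap)) return(rep(1L, nrow(m)))
  adj <- m < gap
  diag(adj) <- TRUE
  oracleComponents(adj)
}

# consensus oracle: units by BFS over union co-membership; categories by
# comparing co-membership matrices of induced sub-partitions
oracleConsensus <- function(members) {
  n <- length(members[[1]])
  co <- lapply(members, function(g) outer(g, g, "=="))
  un <- co[[1]] | co[[2]] | co[[3]]
  unit <- oracleComponents(un)
  out <- list()
  for (u in sort(unique(unit))) {
    idx <- which(unit == u)
    sub <- lapply(co, function(m) m[idx, idx, drop = FALSE])
    eq <- c(identical(sub[[1]], sub[[2]]),
            identical(sub[[1]], sub[[3]]),
            identical(sub[[2]], sub[[3]]))
    cat <- if (all(eq)) "FULL" else if (any(eq)) "PARTIAL" else "DISCORDANT"
    out[[length(out) + 1L]] <- list(idx = idx, category = cat)
  }
  out
}

# independent mixed Yule-coalescent log-likelihood: equivalence classes of
# tips under "MRCA height < h" (via cophenetic distances on an ultrametric
# tree) give lineage counts; one representative tip per OTU gives the
# species-lineage count
oracleGmycLogLik <- function(tree, T, l1, p1, l2, p2) {
  co <- ape::cophenetic.phylo(tree) / 2
  n <- nrow(co)
  classesAt <- function(idx, h) {
    adj <- co[idx, idx, drop = FALSE] < h
    diag(adj) <- TRUE
    max(oracleComponents(adj))
  }
  otu <- oracleComponents(co < T)
  reps <- match(unique(otu), otu)
  nodeH <- sort(unique(round(ape::branching.times(tree), 12)),
                decreasing = TRUE)
  bounds <- sort(unique(c(nodeH, T, 0)), decreasing = TRUE)
  ll <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    up <- bounds[i]; lo <- bounds[i + 1L]
    h <- (up + lo) / 2
    k <- classesAt(reps, h)
    coalSum <- 0
    for (j in unique(otu)) {
      idx <- which(otu == j)
      nj <- if (h >= T) 0 else classesAt(idx, h)
      coalSum <- coalSum + (nj * (nj - 1))^p2
    }
    b <- l1 * k^p1 + l2 * coalSum
    nev <- sum(abs(nodeH - lo) < 1e-12)
    if (lo > 0 && nev > 0) ll <- ll + nev * log(b)
    ll <- ll - b * (up - lo)
  }
  ll
}

# hand-iterated MCL reference (explicit loops)
oracleMcl <- function(sim, r = 2, e = 2, tol = 1e-6, maxIter = 200) {
  n <- nrow(sim)
  M <- sim
  for (i in seq_len(n)) M[i, i] <- max(M[i, i], 1)
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (iter in seq_len(maxIter)) {
    Me <- M
    for (k in seq_len(e - 1)) Me <- Me %*% M
    Mi <- Me^r
    for (j in seq_len(n)) Mi[, j] <- Mi[, j] / sum(Mi[, j])
    Mi[Mi < 1e-12] <- 0
    for (j in seq_len(n)) Mi[, j] <- Mi[, j] / sum(Mi[, j])
    if (max(abs(Mi - M)) < tol) {
      adj <- (Mi > 1e-6) | t(Mi > 1e-6)
      diag(adj) <- TRUE
      return(oracleComponents(adj))
    }
    M <- Mi
  }
  stop("oracle MCL did not converge")
}

# fixture: alignment of n sequences derived from one ancestor with per-site
# substitution probability mutRate (keeps divergences far from saturation)
mutatedAlignment <- function(n, L, mutRate = 0.15, ambig = 0) {
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- anc
    hit <- runif(L) < mutRate
    s[hit] <- sample(bases, sum(hit), replace = TRUE)
    if (ambig > 0) s[runif(L) < ambig] <- sample(c("N", "-"), 1)
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", seq_len(n))
  barcodeAlignment(seqs)
}

# fixture: alignment realizing exact site-pattern counts between two seqs
patternAlignment <- function(nSame, nTs, nTv) {
  a <- c(rep("A", nSame), rep("A", nTs), rep("A", nTv))
  b <- c(rep("A", nSame), rep("G", nTs), rep("C", nTv))
  barcodeAlignment(c(s1 = paste(a, collapse = ""),
                     s2 = paste(b, collapse = "")))
}

# fixture: DistanceMatrix from an explicit symmetric matrix
dmFrom <- function(m, ids = NULL, model = "p") {
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  new("DistanceMatrix", d = m, model = model)
}

# fixture: block distance matrix with given within/between distances
blockDm <- function(sizes, within, between, jitter = 0) {
  n <- sum(sizes)
  grp <- rep(seq_along(sizes), sizes)
  m <- matrix(between, n, n)
  for (g in seq_along(sizes)) {
    idx <- which(grp == g)
    m[idx, idx] <- within
  }
  if (jitter > 0) {
    noise <- matrix(stats::runif(n * n, 0, jitter), n, n)
    noise <- (noise + t(noise)) / 2
    m <- m + noise
  }
  diag(m) <- 0
  dmFrom(m)
}

# fixture: random partition of n items into at most kMax groups
randomGrouping <- function(n, kMax) {
  g <- sample.int(kMax, n, replace = TRUE)
  match(g, unique(g))
}

quietPipelineConfig <- function(alignment, seed, ...) {
  utils::modifyList(
    list(alignment = alignment, seed = seed, logLevel = "quiet"),
    list(...))
}
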