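test_that("the prior grid is geometric with the documented endpoints", {
  g <- abgdPriorGrid(0.001, 0.1, 10)
  expect_length(g, 10)
  expect_equal(g[1], 0.001)
  expect_equal(g[10], 0.1)
  # geometric: constant ratio
  expect_equal(diff(log(g)), rep(log(0.1 / 0.001) / 9, 9))
  expect_equal(abgdPriorGrid(0.001, 0.1, 3), c(0.001, 0.01, 0.1))
  expect_equal(abgdPriorGrid(0.05, 0.05, 1), 0.05)
  expect_error(abgdPriorGrid(0.001, 0.1, 1), "pMin == pMax")
  expect_error(abgdPriorGrid(0, 0.1, 5), "0 < pMin")
})

test_that("gap inference finds constructed gaps and refuses degenerate spreads", {
  set.seed(21)
  dm <- blockDm(c(5, 5), within = 0.003, between = 0.12, jitter = 0.002)
  gap <- abgdInferGap(dm, P = 0.01, X = 1.5)
  expect_false(is.null(gap))
  expect_gt(gap$lower, 0.002)
  expect_lt(gap$lower, 0.01)
  expect_gt(gap$upper, 0.1)

  # all-equal distances: no gap
  dm0 <- dmFrom(matrix(0, 4, 4))
  expect_null(abgdInferGap(dm0, P = 0.01))

  # a continuous spread below the prior has no qualifying gap
  n <- 12
  m <- matrix(0, n, n)
  vals <- seq(0.0005, 0.01, length.out = choose(n, 2))
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  expect_null(abgdInferGap(dmFrom(m), P = 0.02))
})

test_that("initial partition splits at the gap and recursion only refines", {
  set.seed(22)
  dm <- blockDm(c(5, 5, 5), within = 0.004, between = 0.12, jitter = 0.002)
  init <- abgdInitialPartition(dm, P = 0.01)
  expect_equal(nOtu(init), 3L)
  expect_true(samePartition(init,
    newPartition(specimenIds(init), rep(1:3, each = 5), "truth")))

  # no gap: a single OTU
  one <- abgdInitialPartition(dmFrom(matrix(0, 4, 4)), P = 0.01)
  expect_equal(nOtu(one), 1L)

  # nested structure: group A holds two tight trios whose internal gap is
  # masked globally by group B's continuous distance spread, so only the
  # within-group re-analysis can see it
  nested <- matrix(0.2, 18, 18)
  across <- matrix(0, 6, 6)              # group A across-trio: ~0.013
  across[1:3, 4:6] <- seq(0.0122, 0.0138, length.out = 9)
  nested[1:6, 1:6] <- across + t(across)
  nested[1:3, 1:3] <- 0.0015             # trio 1
  nested[4:6, 4:6] <- 0.0015             # trio 2
  fill <- matrix(0, 12, 12)              # group B: dense continuous spread
  fill[upper.tri(fill)] <- seq(0.001, 0.015, length.out = 66)
  nested[7:18, 7:18] <- fill + t(fill)
  diag(nested) <- 0
  dmn <- dmFrom(nested)
  ini <- abgdInitialPartition(dmn, P = 0.005)
  rec <- abgdRecursivePartition(dmn, P = 0.005)
  expect_equal(nOtu(ini), 2L)
  expect_gt(nOtu(rec), nOtu(ini))
  expect_equal(nOtu(rec), 3L)

  # homogeneous cluster: recursive equals initial equals one
  expect_equal(nOtu(abgdRecursivePartition(dmFrom(matrix(0, 5, 5)), 0.01)), 1L)

  # groups below 3 members are never re-split
  tiny <- dmFrom(rbind(c(0, 0.2), c(0.2, 0)))
  # (recursion guard exercised through a 2+2 partition)
  m4 <- matrix(0.2, 4, 4); m4[1, 2] <- m4[2, 1] <- 0.001
  m4[3, 4] <- m4[4, 3] <- 0.001; diag(m4) <- 0
  r4 <- abgdRecursivePartition(dmFrom(m4), P = 0.01)
  expect_equal(nOtu(r4), 2L)
})

test_that("partitions match the exhaustive brute-force gap finder", {
  set.seed(23)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    sizes <- sample(2:8, k, replace = TRUE)
    while (sum(sizes) > 30) sizes <- sizes[-1]
    if (length(sizes) < 2) sizes <- c(3, 3)
    dm <- blockDm(sizes, within = runif(1, 0.001, 0.02),
                  between = runif(1, 0.05, 0.2), jitter = 0.004)
    P <- runif(1, 0.005, 0.04)
    m <- as.matrix(dm)
    mine <- otuAssignments(abgdInitialPartition(dm, P))
    oracle <- oracleAbgdInitial(m, P)
    expect_true(sameGroupingVec(unname(mine), oracle))
  }
})

test_that("initial OTU count is non-increasing in the prior and order-invariant", {
  set.seed(24)
  dm <- blockDm(c(4, 4, 4, 4), within = 0.005, between = 0.1, jitter = 0.01)
  counts <- vapply(abgdPriorGrid(0.001, 0.2, 8),
                   function(P) nOtu(abgdInitialPartition(dm, P)), integer(1))
  expect_true(all(diff(counts) <= 0))

  # shuffling specimen order leaves the set partition unchanged
  m <- as.matrix(dm)
  perm <- sample(nrow(m))
  dmPerm <- dmFrom(m[perm, perm], ids = rownames(m)[perm])
  p1 <- abgdInitialPartition(dm, 0.02)
  p2 <- abgdInitialPartition(dmPerm, 0.02)
  expect_true(samePartition(p1, p2))

  # prior above the largest pairwise distance: a single OTU
  expect_equal(nOtu(abgdInitialPartition(dm, 0.5)), 1L)
})

test_that("the scan reports counts per model and prior with zeros where no gap", {
  set.seed(25)
  ds <- generateBarcodeDataset("separated", seed = 25, nSpecies = 3,
                               sampleSizes = 4)
  scan <- abgdScan(ds$alignment, models = "K2P", nSteps = 8)
  expect_s4_class(scan, "AbgdScan")
  expect_equal(nrow(scan@table), 8L)
  expect_true(all(c("initial", "recursive") %in% names(scan@table)))
  expect_true(all(scan@table$recursive >= scan@table$initial))
  # deep three-species divergence: mid-grid priors agree on 3 OTUs
  mid <- scan@table$P > 0.003 & scan@table$P < 0.05
  expect_true(all(scan@table$initial[mid] == 3L))
  wide <- writeAbgdScan(scan)
  expect_equal(nrow(wide), 2L)    # initial + recursive
  expect_equal(ncol(wide), 2L + 8L)
})
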