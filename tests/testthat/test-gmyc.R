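test_that("UPGMA agglomeration places nodes at half the merge distance", {
  m <- rbind(c(0, 0.2, 0.6), c(0.2, 0, 0.6), c(0.6, 0.6, 0))
  tr <- upgmaTree(dmFrom(m, ids = c("A", "B", "C")))
  bt <- sort(ape::branching.times(tr))
  expect_equal(unname(bt), c(0.1, 0.3), tolerance = 1e-12)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))

  # ultrametric input is reproduced exactly by the UPGMA path metric
  um <- rbind(c(0, 0.1, 0.4, 0.4), c(0.1, 0, 0.4, 0.4),
              c(0.4, 0.4, 0, 0.2), c(0.4, 0.4, 0.2, 0))
  dimnames(um) <- list(paste0("s", 1:4), paste0("s", 1:4))
  tru <- upgmaTree(dmFrom(um))
  co <- ape::cophenetic.phylo(tru)[rownames(um), colnames(um)]
  expect_equal(unname(co), unname(um), tolerance = 1e-12)

  # two taxa: a cherry at half their distance
  t2 <- upgmaTree(dmFrom(rbind(c(0, 0.3), c(0.3, 0))))
  expect_equal(unname(ape::branching.times(t2)), 0.15)
  expect_error(upgmaTree(dmFrom(matrix(0, 1, 1))), "at least 2")
})

test_that("branching intervals count lineages per process (hand enumeration)", {
  # balanced 4-tip tree, node heights {3, 1, 1}; threshold at 2
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  st <- branchingIntervals(tr, T = 2)
  expect_length(st$otus, 2L)
  expect_setequal(st$otus[[1]], c("A", "B"))
  # bounds 3, 2, 1, 0 -> three intervals
  expect_equal(st$x, c(1, 1, 1))
  expect_equal(st$event, c(0, 2, 0))  # both cherry nodes tie at height 1
  expect_equal(st$k, c(2, 2, 2))
  expect_equal(unname(st$N[1, ]), c(0, 0))  # above T: no coalescent lineages
  expect_equal(unname(st$N[2, ]), c(1, 1))  # OTU stems below T
  expect_equal(unname(st$N[3, ]), c(2, 2))

  # T just below the root: the root's two subtrees are the OTUs
  st2 <- branchingIntervals(tr, T = 2.9)
  expect_length(st2$otus, 2L)
  # T just above tips: every tip its own OTU
  st3 <- branchingIntervals(tr, T = 0.5)
  expect_length(st3$otus, 4L)
  expect_error(branchingIntervals(tr, T = 5), "between the tips and the root")
})

test_that("the mixed log-likelihood reduces to pure processes and matches the oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  st <- branchingIntervals(tr, T = 2)
  # hand computation at (l1, p1, l2, p2) = (0.5, 1, 2, 1):
  # b = (1, 1, 1 + 2*2*2) over the three unit intervals, two events at b2
  expect_equal(gmycLogLik(st, 0.5, 1, 2, 1),
               2 * log(1) - (1 + 1 + 9), tolerance = 1e-12)

  # threshold at the tips: coalescent term vanishes -> pure Yule
  stTips <- branchingIntervals(tr, T = 1e-6)
  yule <- function(l1, p1) {
    # intervals (3,1): k=2 ending in 2 events; (1, ~0): k=4
    2 * log(l1 * 2^p1) - (l1 * 2^p1 * 2 + l1 * 4^p1 * 1)
  }
  expect_equal(gmycLogLik(stTips, 0.7, 1.3, 5, 1), yule(0.7, 1.3),
               tolerance = 1e-4)

  # random trees: agreement with the independent oracle
  set.seed(31)
  for (rep in 1:5) {
    rt <- ape::as.phylo(stats::hclust(stats::dist(matrix(rnorm(40), 10)),
                                      "average"))
    rootH <- max(ape::branching.times(rt))
    T <- runif(1, 0.1, 0.9) * rootH
    pars <- c(runif(1, .1, 5), runif(1, .3, 2), runif(1, .1, 5),
              runif(1, .3, 2))
    st <- branchingIntervals(rt, T)
    expect_equal(gmycLogLik(st, pars[1], pars[2], pars[3], pars[4]),
                 oracleGmycLogLik(rt, T, pars[1], pars[2], pars[3], pars[4]),
                 tolerance = 1e-8)
  }
  expect_error(gmycLogLik(st, -1, 1, 1, 1), "positive")
})

test_that("likelihood-ratio test reproduces printed statistics and flags failures", {
  lrt <- likelihoodRatioTest(2495.37, 2539.71)
  expect_equal(lrt$LR, 88.68, tolerance = 1e-9)
  expect_lt(lrt$pValue, 0.001)
  expect_equal(lrt$significance, "***")
  expect_equal(likelihoodRatioTest(2495.37, 2541.51)$LR, 92.28,
               tolerance = 1e-9)
  eq <- likelihoodRatioTest(100, 100)
  expect_equal(eq$LR, 0)
  expect_equal(eq$pValue, 1)
  expect_error(likelihoodRatioTest(100, 90), "negative likelihood ratio")
})

test_that("single-threshold fit recovers clean species structure", {
  ds <- generateBarcodeDataset("separated", seed = 5, nSpecies = 5,
                               sampleSizes = 4)
  fit <- fitSingleThreshold(ds$genealogy)
  expect_s4_class(fit, "GmycFit")
  expect_equal(fit@entities, 5L)
  expect_true(samePartition(fit@partition, ds$truth))
  expect_gte(fit@LR, 0)
  expect_lt(fit@pValue, 0.05)
  expect_true(fit@entityCI[1] <= fit@entities &&
              fit@entities <= fit@entityCI[2])
  # threshold sits inside the barcode gap: below the shallowest species
  # divergence, above the deepest within-species coalescence
  spH <- min(ape::branching.times(ds$speciesTree))
  coalH <- max(vapply(unique(specimenData(ds$alignment)$taxon), function(s) {
    tips <- grep(paste0("^", s, "_"), ds$genealogy$tip.label, value = TRUE)
    if (length(tips) < 2) return(0)
    max(ape::cophenetic.phylo(ds$genealogy)[tips, tips]) / 2
  }, numeric(1)))
  expect_lt(fit@thresholds, spH)
  expect_gt(fit@thresholds, coalH)

  # null-model path equals the mixed likelihood at the degenerate
  # single-process configuration
  heights <- barcodelim:::.checkUltrametric(ds$genealogy)
  null <- barcodelim:::.fitNull(ds$genealogy, heights)
  ntip <- ape::Ntip(ds$genealogy)
  st1 <- barcodelim:::.gmycStructure(ds$genealogy, heights,
                                     rep(1L, ntip), max(heights))
  expect_equal(null$logLik,
               gmycLogLik(st1, 0, 1, null$lambda2, null$p2),
               tolerance = 1e-8)
})

test_that("entity count is monotone in the threshold position", {
  ds <- generateBarcodeDataset("separated", seed = 6, nSpecies = 4,
                               sampleSizes = 3)
  tr <- ds$genealogy
  heights <- barcodelim:::.checkUltrametric(tr)
  cand <- barcodelim:::.candidateThresholds(heights, ape::Ntip(tr))
  ent <- vapply(cand, function(T)
    length(barcodelim:::.otusAtThreshold(tr, heights, T)$groups), integer(1))
  expect_true(all(diff(ent) >= 0))   # entities grow as T moves tip-ward
  expect_equal(ent[1], 2L)           # just below the root: two subtrees
  expect_equal(ent[length(ent)], ape::Ntip(tr))  # below all nodes: singletons
})

test_that("entities step through every node height between root and tips", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:2):2,D:4);")
  heights <- barcodelim:::.checkUltrametric(tr)
  for (info in list(c(3.5, 2), c(2.5, 2), c(1.5, 3), c(0.5, 4))) {
    expect_equal(length(barcodelim:::.otusAtThreshold(tr, heights,
                                                      info[1])$groups),
                 as.integer(info[2]))
  }
})

test_that("the fitted partition is invariant to rescaling branch lengths", {
  ds <- generateBarcodeDataset("separated", seed = 8, nSpecies = 4,
                               sampleSizes = 4)
  f1 <- fitSingleThreshold(ds$genealogy)
  scaled <- ds$genealogy
  scaled$edge.length <- scaled$edge.length * 137
  f2 <- fitSingleThreshold(scaled)
  expect_true(samePartition(f1@partition, f2@partition))
  expect_equal(f2@thresholds / f1@thresholds, 137, tolerance = 1e-6)
})

test_that("multiple-threshold fitting extends the single fit and never coarsens", {
  ds <- generateBarcodeDataset("separated", seed = 9, nSpecies = 4,
                               sampleSizes = 4)
  single <- fitSingleThreshold(ds$genealogy)
  m1 <- fitMultipleThreshold(ds$genealogy, maxThresholds = 1)
  expect_equal(m1@logLik, single@logLik)
  expect_equal(m1@entities, single@entities)

  multi <- fitMultipleThreshold(ds$genealogy, maxThresholds = 4)
  expect_gte(multi@entities, single@entities)
  expect_gte(multi@logLik, single@logLik - 1e-6)
  # one true transition depth: no extra threshold improves by > 2 logL units
  expect_length(multi@thresholds, 1L)
})

test_that("non-ultrametric trees are rejected", {
  expect_error(fitSingleThreshold(ape::read.tree(text = "((A:1,B:2):1,C:9);")),
               "not ultrametric")
})
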