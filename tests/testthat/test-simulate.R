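test_that("Yule species trees are ultrametric, correctly sized, and seed-stable", {
  set.seed(71)
  tr <- simulateSpeciesTree(8, yuleRate = 1)
  expect_equal(ape::Ntip(tr), 8L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_setequal(tr$tip.label, paste0("sp", 1:8))

  set.seed(5); a <- ape::write.tree(simulateSpeciesTree(6))
  set.seed(5); b <- ape::write.tree(simulateSpeciesTree(6))
  expect_identical(a, b)
  expect_error(simulateSpeciesTree(1), "at least 2")
})

test_that("Yule waiting times follow the pure-birth process definition", {
  # with k lineages the next speciation waits Exp(k * rate); for n = 2 the
  # root height is the stop-time stretch, Exp(2 * rate)
  set.seed(72)
  h2 <- replicate(600, max(ape::branching.times(simulateSpeciesTree(2, 2))))
  expect_equal(mean(h2), 1 / 4, tolerance = 4 * sd(h2) / sqrt(600) / (1 / 4))
  # the root of an n-tip tree includes the Exp(rate) origin wait plus the
  # later stages; its mean matches the sum of expectations
  set.seed(73)
  h4 <- replicate(400, max(ape::branching.times(simulateSpeciesTree(4, 1))))
  theory <- 1 / 2 + 1 / 3 + 1 / 4     # stages k = 2, 3 and the stop stretch
  expect_equal(mean(h4), theory, tolerance = 4 * sd(h4) / sqrt(400) / theory)
})

test_that("within-species coalescence matches the target diversity", {
  sp <- ape::read.tree(text = "(sp1:5,sp2:5);")
  set.seed(74)
  d2 <- replicate(400, {
    g <- simulateGenealogy(sp, c(sp1 = 2, sp2 = 1), theta = 0.01)
    ape::cophenetic.phylo(g)["sp1_1", "sp1_2"]
  })
  # expected pairwise divergence ~= theta; two-lineage coalescence is
  # exponential so the sd is about the mean
  expect_equal(mean(d2), 0.01, tolerance = 4 * sd(d2) / sqrt(400) / 0.01)

  # one specimen per species: genealogy topology equals the species tree
  g1 <- simulateGenealogy(sp, c(sp1 = 1, sp2 = 1), theta = 0.01)
  expect_equal(ape::Ntip(g1), 2L)
  expect_equal(max(ape::branching.times(g1)), 5)

  # genealogies are ultrametric and cover every sample
  set.seed(75)
  sp4 <- simulateSpeciesTree(4)
  g4 <- simulateGenealogy(sp4, c(sp1 = 3, sp2 = 1, sp3 = 2, sp4 = 4), 0.01)
  expect_equal(ape::Ntip(g4), 10L)
  expect_true(ape::is.ultrametric(g4, tol = 1e-8))
})

test_that("sequence evolution matches the two-rate substitution model", {
  # zero branch lengths: all sequences identical
  tr <- ape::read.tree(text = "(a:0,b:0);")
  set.seed(76)
  aln0 <- evolveSequences(tr, seqLength = 100, kappa = 4)
  expect_equal(length(unique(as.character(aln0))), 1L)

  # two tips at divergence d: the K2P estimate is consistent
  d <- 0.10
  tr2 <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  set.seed(77)
  est <- replicate(100, {
    aln <- evolveSequences(tr2, seqLength = 654, kappa = 4)
    as.matrix(pairwiseDistances(aln, "K2P"))["a", "b"]
  })
  expect_equal(mean(est), d, tolerance = 4 * sd(est) / sqrt(100) / d)

  # the transition/transversion ratio reflects kappa on long sequences
  kappa <- 6
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  e1 <- exp(-4 * beta * d); e2 <- exp(-2 * (alpha + beta) * d)
  expTs <- 0.25 + 0.25 * e1 - 0.5 * e2
  expTv <- 2 * (0.25 - 0.25 * e1)
  set.seed(78)
  big <- evolveSequences(tr2, seqLength = 10000, kappa = kappa)
  enc <- barcodelim:::.encodeAlignment(big)
  a <- enc[1, ]; b <- enc[2, ]
  ts <- mean((a != b) & abs(a - b) == 2)
  tv <- mean(a != b) - ts
  expect_equal(ts / tv, expTs / expTv, tolerance = 0.15)
})

test_that("generated datasets carry consistent truth, regions, and determinism", {
  ds <- generateBarcodeDataset("separated", seed = 99)
  expect_equal(nSpecimens(ds$alignment), 32L)
  expect_equal(alignmentLength(ds$alignment), 654L)
  expect_equal(nOtu(ds$truth), 8L)
  ann <- specimenData(ds$alignment)
  expect_false(anyNA(ann$region))
  expect_equal(unname(otuAssignments(ds$truth)),
               match(ann$taxon, unique(ann$taxon)))

  ds2 <- generateBarcodeDataset("separated", seed = 99)
  expect_identical(as.character(ds2$alignment), as.character(ds$alignment))

  # byte-identical FASTA under a fixed seed
  f1 <- tempfile(); f2 <- tempfile()
  writeBarcodeFasta(ds$alignment, f1)
  writeBarcodeFasta(ds2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the separated preset realizes a barcode gap recoverable by linkage", {
  for (s in 1:5) {
    ds <- generateBarcodeDataset("separated", seed = s)
    m <- as.matrix(pairwiseDistances(ds$alignment, "p"))
    sp <- specimenData(ds$alignment)$taxon
    same <- outer(sp, sp, "==")
    intra <- m[same & upper.tri(m)]
    inter <- m[!same & upper.tri(m)]
    expect_gt(min(inter), max(intra))          # a realized gap exists
    expect_gt(min(inter), 5 * max(intra) / 2)  # scales well separated
    # truth recoverable by single linkage at any threshold inside the gap
    mid <- (max(intra) + min(inter)) / 2
    sl <- singleLinkagePartition(pairwiseDistances(ds$alignment, "p"), mid)
    expect_true(samePartition(sl, ds$truth))
  }
})

test_that("the hard preset overlaps scales and produces conflicts", {
  conflicts <- 0
  for (s in 1:8) {
    ds <- generateBarcodeDataset("hard", seed = s)
    cfg <- quietPipelineConfig(ds$alignment, seed = s,
                               abgd = list(scan = FALSE))
    r <- runPipeline(cfg, tempfile())
    cats <- vapply(r$consensus@units, `[[`, character(1), "category")
    if (any(cats != "FULL")) conflicts <- conflicts + 1
  }
  expect_gte(conflicts, 4)  # at least half the seeds show discordance
})

test_that("single-population coalescent trees are valid null fixtures", {
  set.seed(80)
  tr <- simulateCoalescentTree(12, theta = 0.02)
  expect_equal(ape::Ntip(tr), 12L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
})
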