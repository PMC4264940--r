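test_that("NJ recovers additive trees exactly and roots at the midpoint", {
  # additive 4-taxon matrix from a known tree
  gen <- ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.05,D:0.3):0.1);")
  m <- ape::cophenetic.phylo(gen)
  tr <- njGuideTree(dmFrom(m[c("A", "B", "C", "D"), c("A", "B", "C", "D")],
                           ids = c("A", "B", "C", "D")))
  co <- ape::cophenetic.phylo(tr)[rownames(m), colnames(m)]
  expect_equal(unname(co), unname(m), tolerance = 1e-9)
  expect_true(ape::is.rooted(tr))

  expect_error(njGuideTree(dmFrom(matrix(0, 2, 2))), "at least 3")

  # on an ultrametric matrix, NJ topology equals UPGMA topology
  set.seed(61)
  ds <- generateBarcodeDataset("separated", seed = 61, nSpecies = 4,
                               sampleSizes = 3)
  m2 <- ape::cophenetic.phylo(ds$genealogy)
  nj <- njGuideTree(dmFrom(m2, ids = rownames(m2)))
  up <- upgmaTree(dmFrom(m2, ids = rownames(m2)))
  expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(up)), 0,
               ignore_attr = TRUE)
})

test_that("monophyly queries follow the MRCA leaf-set definition", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(isMonophyleticGroup(tr, c("A", "B")))
  expect_false(isMonophyleticGroup(tr, c("A", "C")))
  expect_true(isMonophyleticGroup(tr, c("A", "B", "C", "D")))
  expect_true(isMonophyleticGroup(tr, "A"))
  expect_error(isMonophyleticGroup(tr, c("A", "Z")), "unknown tips.*Z")
})

test_that("diagnostic sites are pure, ignore ambiguous columns, and flag singletons", {
  aln <- barcodeAlignment(c(a1 = "AAGAG", a2 = "AAGTG",
                            b1 = "AATAC", b2 = "AATGC"))
  d <- diagnosticSites(aln, c("a1", "a2"), c("b1", "b2"))
  # site 3: A={G}, B={T} disjoint; site 5: {G} vs {C}; site 4 overlaps
  expect_setequal(d$position, c(3L, 5L))
  expect_false(any(d$low_confidence))

  # polymorphic overlap is not diagnostic
  aln2 <- barcodeAlignment(c(a1 = "G", a2 = "T", b1 = "T"))
  expect_equal(nrow(diagnosticSites(aln2, c("a1", "a2"), "b1")), 0L)

  # N or gap in either group masks the column
  aln3 <- barcodeAlignment(c(a1 = "GN", a2 = "GA", b1 = "TA", b2 = "T-"))
  d3 <- diagnosticSites(aln3, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d3$position, 1L)

  # singleton groups qualify but are flagged low-confidence
  d4 <- diagnosticSites(aln, "a1", c("b1", "b2"))
  expect_true(all(d4$low_confidence))

  expect_error(diagnosticSites(aln, c("a1", "b1"), c("b1")), "overlap")
  expect_error(diagnosticSites(aln, character(0), "b1"), "non-empty")
})

test_that("sister pairs are read innermost-first from the guide tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):3,((C:1,D:1):1,(E:1,F:1):1):2);")
  # 2-way split: the single pair
  pr <- sisterPairs(tr, list(c("A", "B"), c("C", "D", "E", "F")))
  expect_length(pr, 1L)
  # 3-way split on the ladder side: CD/EF is the innermost pair
  pr3 <- sisterPairs(tr, list(c("A", "B"), c("C", "D"), c("E", "F")))
  expect_equal(sort(pr3[[1]]), c(2L, 3L))
  expect_length(sisterPairs(tr, list(c("A", "B"))), 0L)
  expect_error(sisterPairs(tr, list(c("A", "Z"), c("B"))), "absent")
})

test_that("sympatry is region-set intersection with strict label checking", {
  expect_true(sympatric(c(x = "SWP"), c(y = "SWP", z = "EYR")))
  expect_false(sympatric(c(x = "SWP"), c(y = "EYR")))
  expect_true(sympatric(c(x = "SWP"), c(y = "SWP")))
  expect_error(sympatric(c(x = NA), c(y = "SWP")), "missing region.*x")
})

test_that("resolution keeps sympatric splits, merges allopatric ones, and logs", {
  # one FULL unit (E,F) and one PARTIAL unit (A..D): ABGD+RESL merge A-D,
  # GMYC proposes the split {A,B} | {C,D}
  ids <- c("A", "B", "C", "D", "E", "F")
  parts <- list(newPartition(ids, c(1, 1, 1, 1, 2, 2), "abgd"),
                newPartition(ids, c(1, 1, 2, 2, 3, 3), "gmyc"),
                newPartition(ids, c(1, 1, 1, 1, 2, 2), "resl"))
  rpt <- consensusReport(parts)
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):2,(E:1,F:1):3);")
  seqs <- c(A = "ACGTAA", B = "ACGTAA", C = "ACTTAA", D = "ACTTAA",
            E = "GGTTAA", F = "GGTTAA")

  sym <- barcodeAlignment(seqs, data.frame(
    region = c("R1", "R1", "R1", "R2", "R3", "R3")))
  resSym <- resolveConsensus(rpt, tr, sym)
  expect_equal(nOtu(resSym@partition), 3L)  # split kept: A,B | C,D | E,F
  expect_equal(resSym@decisions$decision[resSym@decisions$category ==
                                           "PARTIAL"], "SPLIT_KEPT")

  alo <- barcodeAlignment(seqs, data.frame(
    region = c("R1", "R1", "R2", "R2", "R3", "R3")))
  resAlo <- resolveConsensus(rpt, tr, alo)
  expect_equal(nOtu(resAlo@partition), 2L)  # merged: A-D | E,F
  dec <- resAlo@decisions[resAlo@decisions$category == "PARTIAL", ]
  expect_equal(dec$decision, "MERGED")
  expect_false(dec$sympatric)
  # diagnostics and monophyly are reported but never decide
  expect_gte(dec$n_diagnostic, 1)
  expect_true(dec$monophyletic_A)

  # bookkeeping sums to the final count
  bk <- resAlo@bookkeeping
  expect_equal(finalCount(bk[["FULL"]], bk[["PARTIAL"]], bk[["DISCORDANT"]]),
               nOtu(resAlo@partition))
})

test_that("an all-FULL report passes through and resolution is idempotent", {
  ids <- letters[1:6]
  g <- c(1, 1, 2, 2, 3, 3)
  parts <- list(newPartition(ids, g, "abgd"), newPartition(ids, g, "gmyc"),
                newPartition(ids, g, "resl"))
  rpt <- consensusReport(parts)
  tr <- ape::read.tree(text = "((a:1,b:1):2,((c:1,d:1):1,(e:1,f:1):1):1);")
  aln <- barcodeAlignment(stats::setNames(rep("ACGT", 6), ids),
                          data.frame(region = rep("R1", 6)))
  res <- resolveConsensus(rpt, tr, aln)
  expect_true(samePartition(res@partition, parts[[1]]))
  expect_equal(nrow(res@decisions), 0L)

  # idempotence: re-comparing the final partition three ways changes nothing
  fp <- res@partition
  rep2 <- consensusReport(list(fp, fp, fp))
  res2 <- resolveConsensus(rep2, tr, aln)
  expect_true(samePartition(res2@partition, fp))
})

test_that("final-count bookkeeping reproduces printed arithmetic", {
  expect_equal(finalCount(96, c(3, 5, 14), 2), 120L)
  expect_equal(finalCount(7, 0, 0), 7L)
  expect_equal(finalCount(0, 0, 4), 4L)
  expect_error(finalCount(-1, 0, 0), "non-negative")
})

test_that("accumulation curves behave at the extremes and are seed-stable", {
  one <- newPartition(paste0("s", 1:10), rep(1, 10), "final")
  acc1 <- otuAccumulation(one, nPerm = 20, seed = 4)
  expect_true(all(acc1$mean_otus == 1))

  singl <- newPartition(paste0("s", 1:10), 1:10, "final")
  accS <- otuAccumulation(singl, nPerm = 20, seed = 4)
  expect_equal(accS$mean_otus, 1:10)
  expect_true(all(accS$sd_otus == 0))

  mixed <- newPartition(paste0("s", 1:12), rep(1:4, 3), "final")
  a <- otuAccumulation(mixed, nPerm = 50, seed = 9)
  b <- otuAccumulation(mixed, nPerm = 50, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(a$mean_otus) >= 0))
  expect_equal(a$mean_otus[12], 4)
})
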