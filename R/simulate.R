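## Synthetic multi-species barcode data with known truth: Yule species tree,
## within-species Kingman coalescent, two-rate (K80) sequence evolution,
## uneven sampling and region labels. All randomness flows through R's
## seeded integer-state generator, so a seed fixes the full output.

## newick assembly helpers -------------------------------------------------

## node: list(label=) for a tip, or list(left=, right=, h=) for an internal
## node with height h; heights above the sampling time (tips at 0)
.newickFrom <- function(node, parentH) {
  if (!is.null(node$label))
    return(sprintf("%s:%.12g", node$label, parentH))
  sprintf("(%s,%s):%.12g",
          .newickFrom(node$left, node$h),
          .newickFrom(node$right, node$h),
          parentH - node$h)
}

.treeFromNode <- function(root) {
  txt <- sprintf("(%s,%s);",
                 .newickFrom(root$left, root$h),
                 .newickFrom(root$right, root$h))
  ape::read.tree(text = txt)
}

#' Simulate a Yule species tree
#'
#' Pure-birth process started from one lineage and observed, with exactly
#' `nSpecies` extant lineages, at the moment the next speciation would
#' occur: inter-event waiting times are exponential with rate
#' `k * yuleRate` while `k` lineages exist, and the lineage to split is
#' chosen uniformly. Tips are at height 0 and labelled `sp1..spN`.
#'
#' @param nSpecies Number of tips (>= 2).
#' @param yuleRate Speciation rate per lineage per time unit (default 1).
#' @return An ultrametric `phylo`.
#' @export
simulateSpeciesTree <- function(nSpecies, yuleRate = 1) {
  if (nSpecies < 2) stop("need at least 2 species")
  if (yuleRate <= 0) stop("yuleRate must be positive")
  t <- 0
  active <- list(list(label = "L1", birth = 0))
  nodes <- list()
  cnt <- 1L
  for (k in seq_len(nSpecies)) {
    t <- t + stats::rexp(1, k * yuleRate)
    if (k == nSpecies) break
    pick <- sample.int(length(active), 1L)
    parent <- active[[pick]]
    cnt <- cnt + 1L
    kid1 <- list(label = parent$label, birth = t)
    kid2 <- list(label = paste0("L", cnt), birth = t)
    nodes[[length(nodes) + 1L]] <- list(a = kid1$label, b = kid2$label,
                                        time = t)
    active[[pick]] <- kid1
    active[[length(active) + 1L]] <- kid2
  }
  present <- t
  ## rebuild the nested topology from the split records (a label keeps its
  ## name on the left child, so each label's splits are time-ordered)
  build <- function(label, since) {
    ## earliest split of `label` after time `since`
    times <- vapply(nodes, function(nd)
      if (nd$a == label && nd$time > since) nd$time else Inf, numeric(1))
    i <- which.min(times)
    if (!length(times) || is.infinite(times[i]))
      return(list(label = label))
    nd <- nodes[[i]]
    list(left = build(nd$a, nd$time), right = build(nd$b, nd$time),
         h = present - nd$time)
  }
  root <- build("L1", -1)
  tr <- .treeFromNode(list(left = root$left, right = root$right, h = root$h))
  tr$tip.label <- paste0("sp", match(tr$tip.label,
                                     paste0("L", seq_len(nSpecies))))
  tr
}

## Kingman coalescent among labelled lineages; rate for m lineages is
## choose(m,2) * 2/theta so the expected pairwise coalescence height is
## theta/2 (pairwise sequence divergence ~= theta in substitution units).
## Returns a node structure (heights above 0) for >= 2 tips.
.coalesceTips <- function(labels, theta) {
  active <- lapply(labels, function(l) list(label = l, h = 0))
  t <- 0
  while (length(active) > 1L) {
    m <- length(active)
    t <- t + stats::rexp(1, choose(m, 2) * 2 / theta)
    pick <- sample.int(m, 2L)
    joined <- list(left = active[[pick[1L]]], right = active[[pick[2L]]],
                   h = t)
    active <- c(active[-pick], list(joined))
  }
  active[[1L]]
}

## rescale all internal heights of a node structure by factor f
.scaleNode <- function(node, f) {
  if (!is.null(node$label)) return(node)
  list(left = .scaleNode(node$left, f), right = .scaleNode(node$right, f),
       h = node$h * f)
}

#' Simulate a single-population coalescent tree
#'
#' Kingman coalescent genealogy for `n` lineages sampled from one
#' panmictic population, scaled so the expected pairwise divergence is
#' `theta`. This is the null scenario for the mixed Yule-coalescent test
#' (one species, no transition point).
#'
#' @param n Number of tips (>= 3 for model fitting).
#' @param theta Expected pairwise divergence (proportion).
#' @return An ultrametric `phylo` with tips `t1..tn`.
#' @export
simulateCoalescentTree <- function(n, theta = 0.01) {
  if (n < 2) stop("need at least 2 tips")
  root <- .coalesceTips(paste0("t", seq_len(n)), theta)
  .treeFromNode(root)
}

#' Simulate a gene genealogy within a species tree
#'
#' Runs an independent Kingman coalescent among the sampled lineages of each
#' species, with the population scaled so the expected intraspecific
#' pairwise divergence is `theta` (in the substitution units of the species
#' tree), then joins the per-species ancestral lineages at the species-tree
#' divergence heights. When a species' coalescent would outlast its stem
#' (deep coalescence), its event heights are compressed below the stem
#' origin; the separated simulation regime keeps this rare and shallow.
#'
#' @param speciesTree Ultrametric `phylo` from [simulateSpeciesTree()].
#' @param sampleSizes Named (by species tip label) or unnamed integer vector
#'   of specimens per species (support includes 1 and 2 to emulate rarity).
#' @param theta Expected within-species pairwise divergence (proportion).
#' @return Ultrametric `phylo`; tips `"<species>_<i>"`.
#' @export
simulateGenealogy <- function(speciesTree, sampleSizes, theta) {
  if (theta <= 0) stop("theta must be positive")
  sp <- speciesTree$tip.label
  if (is.null(names(sampleSizes))) {
    if (length(sampleSizes) == 1L)
      sampleSizes <- rep(sampleSizes, length(sp))
    names(sampleSizes) <- sp
  }
  if (!all(sp %in% names(sampleSizes)))
    stop("sampleSizes must cover every species")
  heights <- .nodeHeights(speciesTree)
  ntip <- ape::Ntip(speciesTree)
  parentOf <- integer(ntip + speciesTree$Nnode)
  parentOf[speciesTree$edge[, 2L]] <- speciesTree$edge[, 1L]
  ## build nested node structure of the species tree, substituting each tip
  ## with its within-species coalescent subtree
  subtreeFor <- function(node) {
    if (node <= ntip) {
      label <- sp[node]
      m <- sampleSizes[[label]]
      tips <- paste0(label, "_", seq_len(m))
      if (m == 1L) return(list(label = tips))
      sub <- .coalesceTips(tips, theta)
      stemH <- heights[parentOf[node]]
      if (sub$h >= 0.95 * stemH)
        sub <- .scaleNode(sub, 0.9 * stemH / sub$h)
      return(sub)
    }
    kids <- speciesTree$edge[speciesTree$edge[, 1L] == node, 2L]
    list(left = subtreeFor(kids[1L]), right = subtreeFor(kids[2L]),
         h = heights[node])
  }
  root <- subtreeFor(ntip + 1L)
  .treeFromNode(root)
}

#' Evolve sequences along a genealogy under a two-rate model
#'
#' Root sequence uniform over {A,C,G,T}; substitutions accumulate along each
#' branch under the K80 model with transition/transversion rate ratio
#' `kappa`, with branch lengths read as expected substitutions per site
#' (total rate normalized to 1). Output is gap-free and equal-length, so the
#' K2P estimator is the matched distance for these data.
#'
#' @param genealogy A `phylo` with branch lengths in expected substitutions.
#' @param seqLength Sites (default 654, the full-length COI barcode).
#' @param kappa Transition/transversion rate ratio (default 4).
#' @return A [BarcodeAlignment-class] over the genealogy's tips.
#' @export
evolveSequences <- function(genealogy, seqLength = 654, kappa = 4) {
  if (seqLength < 1) stop("seqLength must be positive")
  if (kappa <= 0) stop("kappa must be positive")
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  tsMap <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  mutate <- function(seq, d) {
    if (d <= 0) return(seq)
    e1 <- exp(-4 * beta * d)
    e2 <- exp(-2 * (alpha + beta) * d)
    pTs <- 0.25 + 0.25 * e1 - 0.5 * e2
    pTv <- 0.25 - 0.25 * e1  # each of the two transversion targets
    u <- stats::runif(length(seq))
    out <- seq
    out[u < pTs] <- tsMap[seq[u < pTs]]
    i1 <- u >= pTs & u < pTs + pTv
    i2 <- u >= pTs + pTv & u < pTs + 2 * pTv
    out[i1] <- tv1[seq[i1]]
    out[i2] <- tv2[seq[i2]]
    out
  }
  tree <- ape::reorder.phylo(genealogy, "cladewise")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  seqs <- vector("list", ntip + nnode)
  root <- ntip + 1L
  seqs[[root]] <- sample.int(4L, seqLength, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    seqs[[child]] <- mutate(seqs[[par]], tree$edge.length[e])
  }
  bases <- c("A", "C", "G", "T")
  tipSeqs <- vapply(seq_len(ntip), function(i)
    paste(bases[seqs[[i]]], collapse = ""), character(1))
  names(tipSeqs) <- tree$tip.label
  barcodeAlignment(tipSeqs)
}

## preset parameter sets; "separated" guarantees deep interspecific
## divergence relative to intraspecific diversity, "hard" overlaps the two
## scales so the engines disagree
.presetConfig <- function(preset) {
  switch(preset,
    separated = list(nSpecies = 8, yuleRate = 1, theta = 0.0015,
                     rootDepth = 0.3, minSplitDepth = 0.06,
                     sampleSizes = 4, seqLength = 654, kappa = 4,
                     sympatryFraction = 0.5),
    hard = list(nSpecies = 8, yuleRate = 1, theta = 0.02,
                rootDepth = 0.08, minSplitDepth = NULL,
                sampleSizes = NULL, seqLength = 654, kappa = 4,
                sympatryFraction = 0.5),
    stop("unknown preset: ", preset))
}

## rescale a tree to a fixed root height, then (optionally) floor internal
## node heights at minDepth, preserving parent >= child ordering
.shapeSpeciesTree <- function(tree, rootDepth, minDepth = NULL) {
  h <- .nodeHeights(tree)
  tree$edge.length <- tree$edge.length * rootDepth / max(h)
  if (is.null(minDepth)) return(tree)
  h <- .nodeHeights(tree)
  ntip <- ape::Ntip(tree)
  newH <- h
  nodesByH <- order(h[-seq_len(ntip)]) + ntip
  ## floors are staggered slightly so clamped divergences stay distinct
  stag <- 0
  for (nd in nodesByH) {
    if (h[nd] < minDepth) {
      newH[nd] <- minDepth * (1 + 0.01 * stag)
      stag <- stag + 1
    }
  }
  parentOf <- integer(length(h))
  parentOf[tree$edge[, 2L]] <- tree$edge[, 1L]
  for (nd in nodesByH) {
    p <- parentOf[nd]
    if (p > 0 && newH[p] < newH[nd] + minDepth / 2)
      newH[p] <- newH[nd] + minDepth / 2
  }
  tree$edge.length <- newH[tree$edge[, 1L]] - newH[tree$edge[, 2L]]
  tree
}

#' Generate a synthetic barcode dataset with known truth
#'
#' End-to-end fixture generator: Yule species tree (rescaled to a fixed root
#' depth), per-species sampling, coalescent genealogy, two-rate sequence
#' evolution and region labels. The `"separated"` preset floors species
#' divergences at 0.06 substitutions with intraspecific diversity 0.004 and
#' 4 specimens per species, so the minimum interspecific distance exceeds
#' five times the intraspecific scale in expectation; the `"hard"` preset
#' overlaps the scales (root depth 0.08, theta 0.02) with uneven sampling
#' (geometric, mean 4, support from 1) so singletons and conflicts occur.
#' Region labels exercise the sympatry rule: each cherry of the species tree
#' is sympatric (shared label) with probability `sympatryFraction`,
#' otherwise allopatric.
#'
#' @param preset `"separated"` or `"hard"`.
#' @param seed Integer seed fixing the full output (optional; the current
#'   RNG state is used when NULL).
#' @param ... Overrides for preset fields (`nSpecies`, `theta`,
#'   `sampleSizes`, `seqLength`, `kappa`, `rootDepth`, `minSplitDepth`,
#'   `yuleRate`, `sympatryFraction`).
#' @return List with `alignment` (annotated [BarcodeAlignment-class]),
#'   `truth` ([Partition-class]), `speciesTree`, `genealogy`,
#'   `regions` (per species), `config`.
#' @export
generateBarcodeDataset <- function(preset = c("separated", "hard"),
                                   seed = NULL, ...) {
  preset <- match.arg(preset)
  cfg <- utils::modifyList(.presetConfig(preset), list(...))
  cfg$preset <- preset
  if (!is.null(seed)) set.seed(seed)
  spTree <- simulateSpeciesTree(cfg$nSpecies, cfg$yuleRate)
  spTree <- .shapeSpeciesTree(spTree, cfg$rootDepth, cfg$minSplitDepth)
  sizes <- if (is.null(cfg$sampleSizes)) {
    stats::setNames(1L + stats::rgeom(cfg$nSpecies, 1 / 4),
                    spTree$tip.label)
  } else {
    stats::setNames(rep_len(cfg$sampleSizes, cfg$nSpecies),
                    spTree$tip.label)
  }
  gene <- simulateGenealogy(spTree, sizes, cfg$theta)
  aln <- evolveSequences(gene, cfg$seqLength, cfg$kappa)
  ## regions: every species gets its own label; cherries share with
  ## probability sympatryFraction
  regions <- stats::setNames(paste0("R", seq_len(cfg$nSpecies)),
                             spTree$tip.label)
  heights <- .nodeHeights(spTree)
  ntip <- ape::Ntip(spTree)
  for (nd in (ntip + 1L):(ntip + spTree$Nnode)) {
    kids <- spTree$edge[spTree$edge[, 1L] == nd, 2L]
    if (all(kids <= ntip) && stats::runif(1) < cfg$sympatryFraction)
      regions[spTree$tip.label[kids[2L]]] <-
        regions[spTree$tip.label[kids[1L]]]
  }
  species <- sub("_[0-9]+$", "", specimenIds(aln))
  ann <- specimenData(aln)
  ann$taxon <- species
  ann$region <- unname(regions[species])
  specimenData(aln) <- ann
  list(alignment = aln,
       truth = newPartition(specimenIds(aln), species, "truth"),
       speciesTree = spTree, genealogy = gene, regions = regions,
       config = cfg)
}

#' Write a generated dataset to disk
#'
#' Emits `sequences.fasta`, `metadata.tsv` (specimen_id, taxon, region),
#' `truth.tsv` and `genealogy.nwk` into a directory.
#'
#' @param dataset Result of [generateBarcodeDataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBarcodeFasta(dataset$alignment, file.path(dir, "sequences.fasta"))
  ann <- specimenData(dataset$alignment)
  utils::write.table(
    data.frame(specimen_id = specimenIds(dataset$alignment),
               taxon = ann$taxon, region = ann$region),
    file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(specimen_id = specimenIds(dataset$truth),
               otu = otuAssignments(dataset$truth)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeGuideTree(dataset$genealogy, file.path(dir, "genealogy.nwk"))
  invisible(dir)
}
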