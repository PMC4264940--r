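## Resolution of PARTIAL and DISCORDANT comparison units: sympatry of sister
## OTUs decides (sympatric sisters are kept distinct, allopatric sisters are
## merged); diagnostic nucleotides and monophyly are computed and reported
## as an audit trail but never decide. Includes the NJ guide-tree builder
## and the OTU accumulation curve.

#' Midpoint-rooted neighbor-joining guide tree
#'
#' Standard NJ on the distance matrix, midpoint-rooted so that downstream
#' monophyly and sister-pair queries are well defined (outgroup rooting can
#' be substituted by supplying a pre-rooted tree to the consumers).
#'
#' @param dm A [DistanceMatrix-class] over at least 3 specimens.
#' @return A rooted `phylo`.
#' @export
njGuideTree <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 3L) stop("NJ needs at least 3 specimens")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0  # NJ can emit tiny negatives
  phangorn::midpoint(tr)
}

#' Is a set of tips monophyletic?
#'
#' True iff the set equals the full leaf set of its most recent common
#' ancestor on the (rooted) tree.
#'
#' @param tree A rooted `phylo`.
#' @param tips Character vector of tip labels.
#' @return Logical scalar.
#' @export
isMonophyleticGroup <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing))
    stop("unknown tips: ", paste(missing, collapse = ", "))
  if (length(tips) <= 1L || length(tips) == length(tree$tip.label))
    return(TRUE)
  ape::is.monophyletic(tree, tips)
}

#' Pure diagnostic sites between two groups
#'
#' A position qualifies as a pure diagnostic character when the set of
#' states observed in group A and the set observed in group B are disjoint.
#' Positions where either group shows `N`, `-` or another ambiguity code are
#' ignored. Positions are reported 1-based. Diagnostics involving a
#' singleton group are flagged low-confidence, since their validity is
#' questionable for clusters with few representatives.
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param idsA,idsB Disjoint, non-empty specimen id vectors.
#' @return data.frame with `position`, `statesA`, `statesB`,
#'   `low_confidence`.
#' @export
diagnosticSites <- function(alignment, idsA, idsB) {
  if (!length(idsA) || !length(idsB)) stop("groups must be non-empty")
  if (length(intersect(idsA, idsB)))
    stop("groups overlap: ", paste(intersect(idsA, idsB), collapse = ", "))
  enc <- .encodeAlignment(alignment)
  missing <- setdiff(c(idsA, idsB), rownames(enc))
  if (length(missing))
    stop("ids not in alignment: ", paste(missing, collapse = ", "))
  A <- enc[idsA, , drop = FALSE]
  B <- enc[idsB, , drop = FALSE]
  lowConf <- length(idsA) == 1L || length(idsB) == 1L
  bases <- c("A", "C", "G", "T")
  rows <- list()
  for (pos in seq_len(ncol(enc))) {
    a <- A[, pos]; b <- B[, pos]
    if (anyNA(a) || anyNA(b)) next
    sa <- unique(a); sb <- unique(b)
    if (!length(intersect(sa, sb)))
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos,
        statesA = paste(bases[sort(sa)], collapse = "/"),
        statesB = paste(bases[sort(sb)], collapse = "/"),
        low_confidence = lowConf, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(position = integer(0), statesA = character(0),
                      statesB = character(0), low_confidence = logical(0)))
  do.call(rbind, rows)
}

#' Sister OTU pairs within a unit
#'
#' Returns pairs of candidate sub-OTUs whose union forms a cherry-like split
#' on the guide tree, ordered innermost first (most recent common ancestor
#' closest to the tips). A pair qualifies when the MRCA of its union
#' contains, among the unit's members, exactly the two groups. For a 2-way
#' split the single pair is returned; an unsplit unit yields no pairs. When
#' no pair strictly qualifies (reticulate or paraphyletic arrangements), the
#' pair with the shallowest union MRCA is returned as a fallback so that
#' resolution always progresses.
#'
#' @param tree Rooted guide tree containing all unit members.
#' @param groups List of character vectors (candidate sub-OTUs).
#' @return List of length-2 integer vectors indexing `groups`.
#' @export
sisterPairs <- function(tree, groups) {
  if (length(groups) < 2L) return(list())
  members <- unlist(groups, use.names = FALSE)
  missing <- setdiff(members, tree$tip.label)
  if (length(missing))
    stop("sub-OTU members absent from tree: ",
         paste(missing, collapse = ", "))
  heights <- .nodeHeights(tree)
  pairs <- utils::combn(length(groups), 2L, simplify = FALSE)
  info <- lapply(pairs, function(pr) {
    un <- c(groups[[pr[1L]]], groups[[pr[2L]]])
    mrca <- ape::getMRCA(tree, un)
    clade <- tree$tip.label[phangorn::Descendants(tree, mrca, "tips")[[1L]]]
    list(pair = pr, h = heights[mrca],
         cherry = setequal(intersect(clade, members), un))
  })
  qual <- Filter(function(x) x$cherry, info)
  if (!length(qual)) qual <- info[which.min(vapply(info, `[[`, numeric(1),
                                                   "h"))]
  ord <- order(vapply(qual, `[[`, numeric(1), "h"))
  lapply(qual[ord], `[[`, "pair")
}

#' Sympatry of two OTUs
#'
#' Two OTUs are sympatric when the sets of biogeographic region labels of
#' their members intersect; every member must carry a region label. (Region
#' labels are coarse, so sister OTUs scored sympatric may in reality be
#' microallopatric; the decision log carries this caveat.)
#'
#' @param regionsA,regionsB Character vectors of region labels (one per
#'   member; names taken as specimen ids for error reporting).
#' @return Logical scalar.
#' @export
sympatric <- function(regionsA, regionsB) {
  bad <- c(names(regionsA)[is.na(regionsA) | !nzchar(regionsA)],
           names(regionsB)[is.na(regionsB) | !nzchar(regionsB)])
  if (anyNA(regionsA) || anyNA(regionsB) ||
      !all(nzchar(c(regionsA, regionsB))))
    stop("missing region label for specimens: ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
  length(intersect(unique(regionsA), unique(regionsB))) > 0
}

#' Resolve a consensus report into the final partition
#'
#' FULL units pass through unchanged; DISCORDANT units are collapsed to one
#' OTU each (conflicting results); PARTIAL units are resolved pairwise over
#' the sister pairs of their candidate split (the finest proposed
#' sub-partition), innermost pair first: a sympatric pair is kept as two
#' final OTUs, an allopatric pair is merged into one (this also merges
#' single allopatric specimens into their multi-member sister). Diagnostic
#' sites and monophyly are computed for every tested pair and reported in
#' the decision log, but do not influence decisions.
#'
#' @param report A [ConsensusReport-class].
#' @param tree Rooted guide tree covering all specimens (e.g.
#'   [njGuideTree()] output).
#' @param alignment The [BarcodeAlignment-class]; regions are taken from its
#'   `specimenData` unless `regions` is given.
#' @param regions Optional named character vector specimen id -> region.
#' @return A [ResolutionResult-class].
#' @export
resolveConsensus <- function(report, tree, alignment, regions = NULL) {
  if (is.null(regions)) {
    regions <- stats::setNames(specimenData(alignment)$region,
                               specimenIds(alignment))
  }
  finalGroups <- list()
  decisions <- list()
  bkDetail <- c(FULL = 0, PARTIAL = 0, DISCORDANT = 0,
                PARTIAL_MERGED_PAIRS = 0, PARTIAL_KEPT_PAIRS = 0)
  note <- function(...) {
    decisions[[length(decisions) + 1L]] <<- data.frame(...,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(report@units)) {
    u <- report@units[[i]]
    if (u$category == "FULL") {
      finalGroups[[length(finalGroups) + 1L]] <- u$members
      bkDetail[["FULL"]] <- bkDetail[["FULL"]] + 1
      next
    }
    if (u$category == "DISCORDANT") {
      finalGroups[[length(finalGroups) + 1L]] <- u$members
      bkDetail[["DISCORDANT"]] <- bkDetail[["DISCORDANT"]] + 1
      note(unit = i, category = "DISCORDANT", pair = NA, sympatric = NA,
           decision = "COLLAPSED", n_diagnostic = NA,
           monophyletic_A = NA, monophyletic_B = NA, regions_A = NA,
           regions_B = NA)
      next
    }
    ## PARTIAL: blocks of final OTUs, pairwise sister resolution
    split <- split(u$members, u$finest)
    blocks <- lapply(split, function(mem) list(members = mem,
                                               otus = list(mem)))
    while (length(blocks) > 1L) {
      prs <- sisterPairs(tree, lapply(blocks, `[[`, "members"))
      pr <- prs[[1L]]
      a <- blocks[[pr[1L]]]; b <- blocks[[pr[2L]]]
      regA <- regions[a$members]; regB <- regions[b$members]
      symp <- sympatric(stats::setNames(regA, a$members),
                        stats::setNames(regB, b$members))
      diag <- diagnosticSites(alignment, a$members, b$members)
      monoA <- isMonophyleticGroup(tree, a$members)
      monoB <- isMonophyleticGroup(tree, b$members)
      if (symp) {
        merged <- list(members = c(a$members, b$members),
                       otus = c(a$otus, b$otus))
        bkDetail[["PARTIAL_KEPT_PAIRS"]] <- bkDetail[["PARTIAL_KEPT_PAIRS"]] + 1
        decision <- "SPLIT_KEPT"
      } else {
        merged <- list(members = c(a$members, b$members),
                       otus = list(c(a$members, b$members)))
        bkDetail[["PARTIAL_MERGED_PAIRS"]] <-
          bkDetail[["PARTIAL_MERGED_PAIRS"]] + 1
        decision <- "MERGED"
      }
      note(unit = i, category = "PARTIAL",
           pair = paste(paste(a$members, collapse = ","),
                        paste(b$members, collapse = ","), sep = " | "),
           sympatric = symp, decision = decision,
           n_diagnostic = nrow(diag),
           monophyletic_A = monoA, monophyletic_B = monoB,
           regions_A = paste(unique(regA), collapse = ","),
           regions_B = paste(unique(regB), collapse = ","))
      blocks[[pr[1L]]] <- merged
      blocks <- blocks[-pr[2L]]
    }
    unitOtus <- blocks[[1L]]$otus
    finalGroups <- c(finalGroups, unitOtus)
    bkDetail[["PARTIAL"]] <- bkDetail[["PARTIAL"]] + length(unitOtus)
  }
  ids <- specimenIds(report@partitions[[1L]])
  grp <- integer(length(ids))
  for (g in seq_along(finalGroups))
    grp[match(finalGroups[[g]], ids)] <- g
  part <- newPartition(ids, grp, "final")
  decisions <- if (length(decisions)) do.call(rbind, decisions)
    else data.frame(unit = integer(0), category = character(0),
                    pair = character(0), sympatric = logical(0),
                    decision = character(0), n_diagnostic = integer(0),
                    monophyletic_A = logical(0), monophyletic_B = logical(0),
                    regions_A = character(0), regions_B = character(0))
  new("ResolutionResult", partition = part, decisions = decisions,
      bookkeeping = bkDetail, report = report)
}

#' OTU accumulation curve
#'
#' Randomized specimen-addition orderings: for each permutation, the
#' cumulative number of distinct OTUs encountered as specimens are added one
#' by one; the mean and standard deviation per step are returned.
#' Deterministic for a fixed seed.
#'
#' @param partition A [Partition-class] (typically the final partition).
#' @param nPerm Number of random orderings (>= 1, default 100).
#' @param seed Integer seed.
#' @return data.frame with `specimens`, `mean_otus`, `sd_otus`.
#' @export
otuAccumulation <- function(partition, nPerm = 100, seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  memb <- otuAssignments(partition)
  n <- length(memb)
  set.seed(seed)
  acc <- matrix(0, nPerm, n)
  for (r in seq_len(nPerm)) {
    ord <- sample.int(n)
    acc[r, ] <- cumsum(!duplicated(memb[ord]))
  }
  data.frame(specimens = seq_len(n),
             mean_otus = colMeans(acc),
             sd_otus = apply(acc, 2L, stats::sd))
}
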