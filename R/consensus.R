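## Three-way partition comparison: comparison units (connected blocks across
## methods) and FULL / PARTIAL / DISCORDANT categorization.

#' Comparison units across three partitions
#'
#' Units are the connected components of the union graph in which each
#' method contributes edges between co-clustered specimens (the join of the
#' three partitions). Every OTU of every method lies entirely within one
#' unit, so units can be categorized independently.
#'
#' @param partitions List of exactly 3 [Partition-class] objects over
#'   identical specimen sets.
#' @return List of units; each has `members` (specimen ids, input order),
#'   `sub` (list of induced sub-partition integer vectors, one per method).
#' @export
comparisonUnits <- function(partitions) {
  if (length(partitions) != 3L)
    stop("exactly three partitions are compared")
  ids <- specimenIds(partitions[[1L]])
  for (p in partitions[-1L]) {
    dif <- c(setdiff(ids, specimenIds(p)), setdiff(specimenIds(p), ids))
    if (length(dif))
      stop("mismatched specimen sets: ", paste(dif, collapse = ", "))
  }
  n <- length(ids)
  edges <- do.call(rbind, lapply(partitions, function(p) {
    memb <- .membershipFor(p, ids)
    do.call(rbind, lapply(split(seq_len(n), memb), function(idx) {
      if (length(idx) < 2L) return(NULL)
      cbind(idx[-length(idx)], idx[-1L])  # chain suffices for connectivity
    }))
  }))
  unit <- .components(n, edges)
  lapply(split(seq_len(n), unit), function(idx) {
    list(members = ids[idx],
         sub = lapply(partitions, function(p)
           .canonicalGroups(.membershipFor(p, ids[idx]))))
  })
}

#' Categorize a comparison unit
#'
#' FULL when all three induced sub-partitions are identical; PARTIAL when
#' exactly two are identical (the agreeing pair defines the majority
#' sub-partition); DISCORDANT when all three are pairwise different. The
#' finest proposed sub-partition (most OTUs; majority first on ties) is
#' carried as the candidate split for the resolution stage.
#'
#' @param unit A unit from [comparisonUnits()].
#' @return The unit with `category`, `majority` and `finest` fields added.
#' @export
categorizeUnit <- function(unit) {
  s <- unit$sub
  eq12 <- .sameGrouping(s[[1L]], s[[2L]])
  eq13 <- .sameGrouping(s[[1L]], s[[3L]])
  eq23 <- .sameGrouping(s[[2L]], s[[3L]])
  nEq <- sum(eq12, eq13, eq23)
  if (nEq == 3L) {
    unit$category <- "FULL"
    unit$majority <- s[[1L]]
  } else if (nEq == 1L) {
    unit$category <- "PARTIAL"
    unit$majority <- if (eq12) s[[1L]] else if (eq13) s[[1L]] else s[[2L]]
  } else if (nEq == 0L) {
    unit$category <- "DISCORDANT"
    unit$majority <- s[[1L]]
  } else {
    # two pairs equal forces all three equal; unreachable for valid input
    stop("inconsistent sub-partition equalities")
  }
  counts <- vapply(s, max, integer(1))
  cand <- s[[which.max(counts)]]
  if (max(unit$majority) >= max(counts)) cand <- unit$majority
  unit$finest <- cand
  unit
}

#' Build a consensus report from three method partitions
#'
#' @param partitions List of 3 [Partition-class] objects (e.g. ABGD initial
#'   K2P, GMYC single-threshold, RESL) over the same specimens.
#' @return A [ConsensusReport-class].
#' @export
consensusReport <- function(partitions) {
  units <- lapply(comparisonUnits(partitions), categorizeUnit)
  new("ConsensusReport", units = unname(units), partitions = partitions,
      methods = vapply(partitions, methodTag, character(1)))
}

#' Per-category OTU counts and percentages
#'
#' FULL units contribute one OTU each (all methods agree the unit is one
#' OTU); PARTIAL units contribute the OTU count of their majority (default)
#' or finest sub-partition; DISCORDANT units contribute one OTU each.
#' Percentages are over the total.
#'
#' @param report A [ConsensusReport-class].
#' @param partialUse `"majority"` (default) or `"finest"`.
#' @return data.frame with `category`, `otus`, `pct` rows for FULL, PARTIAL,
#'   DISCORDANT.
#' @export
categoryCounts <- function(report, partialUse = c("majority", "finest")) {
  partialUse <- match.arg(partialUse)
  counts <- c(FULL = 0, PARTIAL = 0, DISCORDANT = 0)
  for (u in report@units) {
    counts[[u$category]] <- counts[[u$category]] + switch(u$category,
      FULL = max(u$sub[[1L]]),
      PARTIAL = max(u[[partialUse]]),
      DISCORDANT = 1)
  }
  data.frame(category = names(counts), otus = unname(counts),
             pct = unname(categoryPercentages(counts)),
             stringsAsFactors = FALSE)
}

#' Write a consensus report table
#'
#' One row per comparison unit: unit id, members, category, and the induced
#' OTU ids under each method.
#'
#' @param report A [ConsensusReport-class].
#' @param path Optional output TSV path.
#' @return The data.frame, invisibly when written.
#' @export
writeConsensusReport <- function(report, path = NULL) {
  rows <- lapply(seq_along(report@units), function(i) {
    u <- report@units[[i]]
    subs <- vapply(u$sub, function(s) paste(s, collapse = ","), character(1))
    data.frame(unit = i, members = paste(u$members, collapse = ","),
               category = u$category,
               stats::setNames(as.list(subs), report@methods),
               stringsAsFactors = FALSE, check.names = FALSE)
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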