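## Internal helpers shared across modules.

#' Construct a canonical Partition
#'
#' Builds a [Partition-class] from specimen ids and an arbitrary grouping
#' vector, renumbering OTUs by the input order of each OTU's first member so
#' that two partitions inducing the same grouping are identical objects.
#'
#' @param ids Character vector of specimen ids.
#' @param groups Vector (any type) of group labels, parallel to `ids`.
#' @param method Method tag.
#' @return A [Partition-class].
#' @export
#' @examples
#' newPartition(c("a", "b", "c"), c("x", "y", "x"), "demo")
newPartition <- function(ids, groups, method = "unknown") {
  stopifnot(length(ids) == length(groups))
  otu <- match(groups, unique(groups))
  new("Partition", ids = as.character(ids), otu = as.integer(otu),
      method = as.character(method))
}

## membership integer vector in the order of `ids` for a Partition possibly
## ordered differently
.membershipFor <- function(partition, ids) {
  m <- otuAssignments(partition)
  if (!all(ids %in% names(m)))
    stop("partition does not cover the requested specimen set")
  unname(m[ids])
}

## canonical relabel of an integer grouping vector (first occurrence order)
.canonicalGroups <- function(g) match(g, unique(g))

## TRUE if two grouping vectors (parallel to the same id order) induce the
## same set partition
.sameGrouping <- function(a, b) {
  identical(.canonicalGroups(a), .canonicalGroups(b))
}

## connected components of an undirected graph on n vertices given a 2-col
## edge matrix (indices); returns integer membership 1..k canonicalized by
## first vertex
.components <- function(n, edges) {
  if (n == 0L) return(integer(0))
  if (is.null(edges) || nrow(edges) == 0L) return(seq_len(n))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  .canonicalGroups(as.integer(memb))
}

## components of the graph with edges where dmat < threshold (strict)
.componentsBelow <- function(dmat, threshold) {
  n <- nrow(dmat)
  idx <- which(upper.tri(dmat) & dmat < threshold, arr.ind = TRUE)
  .components(n, idx)
}

## restrict a Partition to a subset of ids, returning canonical integer groups
.inducedGroups <- function(partition, ids) {
  .canonicalGroups(.membershipFor(partition, ids))
}

#' Final OTU count from resolution bookkeeping
#'
#' Sums per-category final OTU contributions: FULL units pass through one
#' OTU each, PARTIAL units contribute their resolved counts (merged
#' allopatric groups count one, kept sympatric sisters count one each), and
#' DISCORDANT units are collapsed to one OTU each.
#'
#' @param full Number of final OTUs from FULL units.
#' @param partial Numeric vector of final OTU contributions from PARTIAL
#'   units (any breakdown; it is summed).
#' @param discordant Number of final OTUs from DISCORDANT units.
#' @return Integer total.
#' @export
#' @examples
#' finalCount(96, c(3, 5, 14), 2)  # 120
finalCount <- function(full, partial = 0, discordant = 0) {
  counts <- c(full, partial, discordant)
  if (any(counts < 0)) stop("bookkeeping counts must be non-negative")
  as.integer(sum(counts))
}

## internal: total from a bookkeeping vector carrying FULL/PARTIAL/DISCORDANT
finalCountFromBookkeeping <- function(bk) {
  finalCount(bk[["FULL"]], bk[["PARTIAL"]], bk[["DISCORDANT"]])
}

#' Category percentages for a concordance summary
#'
#' Converts per-category OTU counts into percentages of the total.
#'
#' @param counts Named numeric vector of OTU counts per category.
#' @return Named numeric vector of percentages (0-100 scale).
#' @export
#' @examples
#' categoryPercentages(c(FULL = 96, PARTIAL = 22, DISCORDANT = 2))
categoryPercentages <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  100 * counts / sum(counts)
}
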