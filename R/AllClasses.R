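#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet width
#' @importClassesFrom Biostrings DNAStringSet
NULL

setOldClass("phylo")

#' Aligned barcode sequences with specimen annotations
#'
#' Container for an alignment of equal-length DNA barcode sequences keyed by
#' specimen id, together with per-specimen annotations (taxon label,
#' biogeographic region, coordinates). All delimitation engines operate on
#' this object.
#'
#' @slot seqs A [Biostrings::DNAStringSet] of equal-width sequences; names are
#'   specimen ids (unique, non-empty).
#' @slot specimenData A [S4Vectors::DataFrame] with one row per specimen and
#'   columns `taxon`, `region`, `lat`, `lon` (NA where unknown).
#'
#' @seealso [readBarcodeFasta()], [attachMetadata()], [collapseHaplotypes()]
#' @exportClass BarcodeAlignment
setClass("BarcodeAlignment",
  representation(seqs = "DNAStringSet", specimenData = "DataFrame"))

setValidity("BarcodeAlignment", function(object) {
  ids <- names(object@seqs)
  if (length(object@seqs) == 0L)
    return("alignment contains no records")
  if (is.null(ids) || any(!nzchar(ids)))
    return("every specimen must have a non-empty id")
  if (anyDuplicated(ids))
    return(paste0("duplicate specimen id: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- Biostrings::width(object@seqs)
  if (length(unique(w)) > 1L) {
    bad <- ids[w != w[1L]]
    return(paste0("unequal length sequences: ", paste(bad, collapse = ", ")))
  }
  if (w[1L] == 0L)
    return("sequences must have length > 0")
  if (nrow(object@specimenData) != length(object@seqs))
    return("specimenData must have one row per specimen")
  TRUE
})

#' Partition of specimens into OTUs
#'
#' A labelled assignment of every specimen to exactly one operational
#' taxonomic unit (OTU). This is the universal output type of the three
#' delimitation engines and of the resolution stage. OTU ids are canonical:
#' integers numbered by the input order of each OTU's first member.
#'
#' @slot ids Character vector of specimen ids (input order).
#' @slot otu Integer vector of OTU ids, parallel to `ids`, values `1..k`
#'   contiguous.
#' @slot method Method tag, e.g. `"abgd"`, `"gmyc"`, `"resl"`, `"final"`.
#'
#' @exportClass Partition
setClass("Partition",
  representation(ids = "character", otu = "integer", method = "character"))

setValidity("Partition", function(object) {
  if (length(object@ids) != length(object@otu))
    return("ids and otu must have equal length")
  if (length(object@ids) == 0L)
    return("empty partition")
  if (anyDuplicated(object@ids))
    return("duplicate specimen ids in partition")
  if (anyNA(object@otu) || any(object@otu < 1L))
    return("OTU ids must be positive integers")
  k <- max(object@otu)
  if (!identical(sort(unique(object@otu)), seq_len(k)))
    return("OTU ids must be contiguous 1..k")
  # canonical: OTUs numbered by first appearance
  if (!identical(unique(object@otu), sort(unique(object@otu))))
    return("partition not canonicalized (OTUs must be numbered by first member)")
  if (length(object@method) != 1L)
    return("method must be a single string")
  TRUE
})

#' Pairwise distance matrix under a named substitution model
#'
#' Symmetric matrix of pairwise distances on the proportion scale (never
#' percent: the BIN threshold of 2.2% is written 0.022), computed under one
#' of the models `p`, `JC69` or `K2P` with pairwise deletion of sites
#' containing `N` or `-`.
#'
#' @slot d Symmetric numeric matrix with zero diagonal; dimnames are
#'   specimen ids.
#' @slot model One of `"p"`, `"JC69"`, `"K2P"`.
#'
#' @seealso [pairwiseDistances()]
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(d = "matrix", model = "character"))

setValidity("DistanceMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("matrix must carry identical row/column specimen ids")
  if (any(!is.finite(d))) return("all distances must be finite")
  if (any(d < 0)) return("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-12) return("matrix must be symmetric")
  if (!object@model %in% c("p", "JC69", "K2P"))
    return("model must be one of p, JC69, K2P")
  TRUE
})

#' ABGD scan over models and prior divergence values
#'
#' Holds, for each (model, prior P) combination, the OTU counts of the
#' initial and recursive ABGD partitions plus the partitions themselves, in
#' the layout of a published ABGD scan table (a `0` count marks a prior at
#' which no barcode gap was found).
#'
#' @slot table data.frame with columns `model`, `P`, `initial`, `recursive`.
#' @slot partitions Named list of [Partition-class] objects (or NULL where no
#'   gap), names `"<model>|<P>|<initial|recursive>"`.
#' @slot params List of scan parameters (grid, X, slope window).
#'
#' @seealso [abgdScan()]
#' @exportClass AbgdScan
setClass("AbgdScan",
  representation(table = "data.frame", partitions = "list", params = "list"))

#' Fitted general mixed Yule-coalescent model
#'
#' Result of fitting the mixed Yule-coalescent model to an ultrametric tree:
#' a threshold height (or several, for the multiple-threshold model)
#' separating diversification from coalescent branching, rate and exponent
#' parameters for the two processes, log-likelihoods of the mixed and null
#' (single-process) models, the likelihood-ratio statistic, and the implied
#' OTU partition.
#'
#' @slot tree The input ultrametric tree (`phylo`).
#' @slot rates Named numeric: `lambda1` (diversification), `lambda2`
#'   (coalescent).
#' @slot exponents Named numeric: `p1`, `p2` scaling exponents.
#' @slot thresholds Threshold height(s), time units of the tree, tips at 0.
#' @slot logLik,nullLogLik Log-likelihood of the mixed and null models.
#' @slot LR Likelihood-ratio statistic `2 * (logLik - nullLogLik)`.
#' @slot pValue P-value of the likelihood-ratio test.
#' @slot clusters Number of multi-member OTUs.
#' @slot entities Total OTU count (clusters plus singletons).
#' @slot clusterCI,entityCI Integer ranges over candidate thresholds within 2
#'   log-likelihood units of the optimum.
#' @slot partition The implied [Partition-class] (tip labels).
#' @slot candidates data.frame of all candidate thresholds with their
#'   maximized log-likelihoods and OTU counts.
#' @slot model `"single"` or `"multiple"`.
#'
#' @seealso [fitSingleThreshold()], [fitMultipleThreshold()]
#' @exportClass GmycFit
setClass("GmycFit",
  representation(tree = "phylo", rates = "numeric", exponents = "numeric",
                 thresholds = "numeric", logLik = "numeric",
                 nullLogLik = "numeric", LR = "numeric", pValue = "numeric",
                 clusters = "integer", entities = "integer",
                 clusterCI = "integer", entityCI = "integer",
                 partition = "Partition", candidates = "data.frame",
                 model = "character"))

setValidity("GmycFit", function(object) {
  if (object@entities < object@clusters)
    return("entities must be >= clusters")
  if (object@LR < -1e-6)
    return("likelihood ratio must be non-negative up to tolerance")
  TRUE
})

#' Three-way partition concordance report
#'
#' Comparison units (connected blocks of specimens across the three method
#' partitions) with their induced sub-partitions and concordance category:
#' FULL (all three methods agree), PARTIAL (exactly two agree) or DISCORDANT
#' (all three differ).
#'
#' @slot units List; each element has `members`, `sub` (list of induced
#'   sub-partition integer vectors, one per method), `category`, `majority`
#'   and `finest` (sub-partition proposals used downstream).
#' @slot partitions The three input [Partition-class] objects.
#' @slot methods Character vector of method tags, parallel to `partitions`.
#'
#' @seealso [consensusReport()], [categoryCounts()]
#' @exportClass ConsensusReport
setClass("ConsensusReport",
  representation(units = "list", partitions = "list", methods = "character"))

#' Resolved final partition with decision audit trail
#'
#' Output of the resolution stage: the final OTU partition after applying
#' the sympatry rule to PARTIAL units (and collapsing DISCORDANT units),
#' the per-decision log (sister pair, region sets, sympatry, decision,
#' diagnostic-site and monophyly reports), and bookkeeping of final OTU
#' counts per source category.
#'
#' @slot partition Final [Partition-class] (method `"final"`).
#' @slot decisions data.frame decision log.
#' @slot bookkeeping Named numeric of final OTU counts:
#'   `FULL`, `PARTIAL`, `DISCORDANT` (plus detail entries).
#' @slot report The input [ConsensusReport-class].
#'
#' @seealso [resolveConsensus()], [finalCount()]
#' @exportClass ResolutionResult
setClass("ResolutionResult",
  representation(partition = "Partition", decisions = "data.frame",
                 bookkeeping = "numeric", report = "ConsensusReport"))

## ------------------------------------------------------------------------
## Generics

#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))
#' @export
setGeneric("nSpecimens", function(x) standardGeneric("nSpecimens"))
#' @export
setGeneric("alignmentLength", function(x) standardGeneric("alignmentLength"))
#' @export
setGeneric("specimenData", function(x) standardGeneric("specimenData"))
#' @export
setGeneric("specimenData<-", function(x, value) standardGeneric("specimenData<-"))
#' @export
setGeneric("nOtu", function(x) standardGeneric("nOtu"))
#' @export
setGeneric("otuAssignments", function(x) standardGeneric("otuAssignments"))
#' @export
setGeneric("methodTag", function(x) standardGeneric("methodTag"))
#' @export
setGeneric("distModel", function(x) standardGeneric("distModel"))

## ------------------------------------------------------------------------
## Accessors

#' @describeIn BarcodeAlignment-class Specimen ids, in input order.
#' @param x object.
#' @export
setMethod("specimenIds", "BarcodeAlignment", function(x) names(x@seqs))

#' @describeIn BarcodeAlignment-class Number of specimens.
#' @export
setMethod("nSpecimens", "BarcodeAlignment", function(x) length(x@seqs))

#' @describeIn BarcodeAlignment-class Number of alignment columns.
#' @export
setMethod("alignmentLength", "BarcodeAlignment",
          function(x) Biostrings::width(x@seqs)[1L])

#' @describeIn BarcodeAlignment-class Per-specimen annotation table.
#' @export
setMethod("specimenData", "BarcodeAlignment", function(x) x@specimenData)

#' @describeIn BarcodeAlignment-class Replace the annotation table.
#' @param value replacement DataFrame.
#' @export
setReplaceMethod("specimenData", "BarcodeAlignment", function(x, value) {
  x@specimenData <- value
  validObject(x)
  x
})

#' @export
#' @describeIn BarcodeAlignment-class Sequences as a named character vector.
setMethod("as.character", "BarcodeAlignment",
          function(x) as.character(x@seqs))

setMethod("show", "BarcodeAlignment", function(object) {
  cat("BarcodeAlignment with", nSpecimens(object), "specimens,",
      alignmentLength(object), "columns\n")
  ann <- object@specimenData
  filled <- vapply(c("taxon", "region"), function(cn)
    sum(!is.na(ann[[cn]])), integer(1))
  cat("  annotations: taxon", filled[["taxon"]], "| region",
      filled[["region"]], "\n")
})

#' @describeIn Partition-class Specimen ids.
#' @param x object.
#' @export
setMethod("specimenIds", "Partition", function(x) x@ids)

#' @describeIn Partition-class Number of OTUs.
#' @export
setMethod("nOtu", "Partition", function(x) max(x@otu))

#' @describeIn Partition-class Named integer vector specimen id -> OTU id.
#' @export
setMethod("otuAssignments", "Partition",
          function(x) stats::setNames(x@otu, x@ids))

#' @describeIn Partition-class Method tag.
#' @export
setMethod("methodTag", "Partition", function(x) x@method)

setMethod("show", "Partition", function(object) {
  cat("Partition [", object@method, "]: ", length(object@ids),
      " specimens in ", nOtu(object), " OTUs\n", sep = "")
  sizes <- tabulate(object@otu)
  cat("  singletons:", sum(sizes == 1L),
      "| largest OTU:", max(sizes), "\n")
})

#' @describeIn DistanceMatrix-class Distance model name.
#' @param x object.
#' @export
setMethod("distModel", "DistanceMatrix", function(x) x@model)

#' @describeIn DistanceMatrix-class Specimen ids.
#' @export
setMethod("specimenIds", "DistanceMatrix", function(x) rownames(x@d))

#' @export
#' @describeIn DistanceMatrix-class Extract the plain numeric matrix.
setMethod("as.matrix", "DistanceMatrix", function(x) x@d)

setMethod("show", "DistanceMatrix", function(object) {
  v <- object@d[upper.tri(object@d)]
  cat("DistanceMatrix (", object@model, "): ", nrow(object@d),
      " specimens, ", length(v), " pairs\n", sep = "")
  if (length(v))
    cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
                min(v), max(v), mean(v)))
})

setMethod("show", "AbgdScan", function(object) {
  cat("AbgdScan:", length(unique(object@table$model)), "model(s) x",
      length(unique(object@table$P)), "prior values\n")
  print(utils::head(object@table, 12))
})

setMethod("show", "GmycFit", function(object) {
  cat("GmycFit (", object@model, " threshold)\n", sep = "")
  cat(sprintf("  clusters %d (%d-%d)  entities %d (%d-%d)\n",
              object@clusters, object@clusterCI[1], object@clusterCI[2],
              object@entities, object@entityCI[1], object@entityCI[2]))
  cat(sprintf("  logL null %.2f  logL GMYC %.2f  LR %.2f (p = %.3g)\n",
              object@nullLogLik, object@logLik, object@LR, object@pValue))
  cat("  threshold(s):", paste(signif(object@thresholds, 6), collapse = ", "),
      "\n")
})

setMethod("show", "ConsensusReport", function(object) {
  cats <- vapply(object@units, function(u) u$category, character(1))
  cat("ConsensusReport:", length(object@units), "comparison units (",
      paste(names(table(cats)), table(cats), collapse = ", "), ")\n")
})

setMethod("show", "ResolutionResult", function(object) {
  bk <- object@bookkeeping
  cat("ResolutionResult: final count", finalCountFromBookkeeping(bk), "OTUs\n")
  cat(sprintf("  FULL %d | PARTIAL %d | DISCORDANT %d\n",
              bk[["FULL"]], bk[["PARTIAL"]], bk[["DISCORDANT"]]))
})
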