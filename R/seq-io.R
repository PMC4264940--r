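## Sequence, metadata, tree and table I/O, plus haplotype collapsing.

#' Read an aligned FASTA file of barcode sequences
#'
#' Reads equal-length DNA sequences from FASTA. Ids are taken from the header
#' up to the first whitespace; sequences are uppercased. The file must
#' contain at least one record, ids must be unique, and all sequences must
#' have the same length (the input is an alignment, typically the 654 bp COI
#' barcode region).
#'
#' @param path Path to a FASTA file.
#' @return A [BarcodeAlignment-class] with empty annotations.
#' @export
readBarcodeFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) == 0L) stop("no records in FASTA file: ", path)
  first <- lines[nonEmpty[1L]]
  if (!startsWith(trimws(first), ">"))
    stop("malformed FASTA at line ", nonEmpty[1L],
         ": expected '>' header, got '", substr(first, 1, 30), "'")
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA: ",
                                            conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  barcodeAlignment(seqs)
}

#' Construct a BarcodeAlignment from sequences
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector
#'   of equal-length sequences over `{A,C,G,T,N,-}` (other IUPAC codes are
#'   accepted and treated as N by the distance module).
#' @param specimenData Optional DataFrame/data.frame with columns among
#'   `taxon`, `region`, `lat`, `lon`, one row per specimen.
#' @return A [BarcodeAlignment-class].
#' @export
barcodeAlignment <- function(seqs, specimenData = NULL) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  ids <- names(seqs)
  if (is.null(ids)) stop("sequences must be named by specimen id")
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L)
    stop("unequal length sequences: ",
         paste(ids[w != stats::median(w)], collapse = ", "))
  if (is.null(specimenData)) {
    specimenData <- S4Vectors::DataFrame(
      taxon = rep(NA_character_, length(seqs)),
      region = rep(NA_character_, length(seqs)),
      lat = rep(NA_real_, length(seqs)),
      lon = rep(NA_real_, length(seqs)))
  } else {
    specimenData <- as(as.data.frame(specimenData), "DataFrame")
    for (cn in c("taxon", "region")) if (is.null(specimenData[[cn]]))
      specimenData[[cn]] <- rep(NA_character_, length(seqs))
    for (cn in c("lat", "lon")) if (is.null(specimenData[[cn]]))
      specimenData[[cn]] <- rep(NA_real_, length(seqs))
  }
  rownames(specimenData) <- ids
  new("BarcodeAlignment", seqs = seqs, specimenData = specimenData)
}

#' Attach specimen metadata from a TSV table
#'
#' Reads a tab-separated table with a mandatory `specimen_id` column and any
#' of `taxon`, `region`, `lat`, `lon`, and attaches the annotations to the
#' alignment by id. Specimens absent from the table keep empty annotations;
#' table rows whose id is not in the alignment are dropped with a warning.
#' Region labels are free strings (the assignment of specimens to
#' biogeographic subregions is the user's responsibility).
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param path Path to the metadata TSV.
#' @return The annotated alignment.
#' @export
attachMetadata <- function(alignment, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"specimen_id" %in% names(tab))
    stop("metadata table must contain a 'specimen_id' column")
  ids <- specimenIds(alignment)
  extra <- setdiff(tab$specimen_id, ids)
  if (length(extra))
    warning("metadata rows dropped (ids not in alignment): ",
            paste(extra, collapse = ", "))
  tab <- tab[tab$specimen_id %in% ids, , drop = FALSE]
  ann <- specimenData(alignment)
  hit <- match(ids, tab$specimen_id)
  for (cn in intersect(c("taxon", "region"), names(tab)))
    ann[[cn]] <- ifelse(is.na(hit), ann[[cn]], as.character(tab[[cn]])[hit])
  for (cn in intersect(c("lat", "lon"), names(tab)))
    ann[[cn]] <- ifelse(is.na(hit), ann[[cn]], as.numeric(tab[[cn]])[hit])
  specimenData(alignment) <- ann
  alignment
}

#' Collapse identical sequences to haplotypes
#'
#' Merges string-identical sequences into a single representative (the first
#' member in input order), as done before tree-based analyses so that
#' zero-length terminal branches do not degrade the mixed Yule-coalescent
#' fit. The returned mapping is a partition of all specimen ids; expanding a
#' downstream partition of haplotypes through it restores full specimen
#' coverage (see [expandPartition()]).
#'
#' @param alignment A [BarcodeAlignment-class].
#' @return List with `alignment` (collapsed; haplotype ids are the
#'   representative specimen ids) and `members` (named list haplotype id ->
#'   character vector of member specimen ids).
#' @export
collapseHaplotypes <- function(alignment) {
  seqs <- as.character(alignment@seqs)
  ids <- specimenIds(alignment)
  key <- match(seqs, unique(seqs))
  members <- split(ids, key)
  reps <- vapply(members, `[`, character(1), 1L)
  names(members) <- reps
  ord <- order(match(reps, ids))  # haplotypes in input order of representative
  members <- members[ord]
  reps <- reps[ord]
  keep <- match(reps, ids)
  collapsed <- barcodeAlignment(alignment@seqs[keep],
                                specimenData(alignment)[keep, , drop = FALSE])
  list(alignment = collapsed, members = members)
}

#' Expand a haplotype-level partition back to specimens
#'
#' @param partition A [Partition-class] over haplotype ids.
#' @param members The haplotype membership map from [collapseHaplotypes()].
#' @param ids Optional character vector giving the specimen output order
#'   (defaults to the order implied by `members`).
#' @return A [Partition-class] over all member specimen ids.
#' @export
expandPartition <- function(partition, members, ids = NULL) {
  hap <- otuAssignments(partition)
  if (!setequal(names(hap), names(members)))
    stop("partition ids do not match haplotype map")
  specimen <- unlist(members, use.names = FALSE)
  grp <- rep(unname(hap[names(members)]),
             lengths(members))
  if (is.null(ids)) ids <- specimen
  ord <- match(ids, specimen)
  if (anyNA(ord)) stop("requested ids not covered by haplotype map")
  newPartition(ids, grp[ord], methodTag(partition))
}

#' Read a rooted tree from a Newick file or string
#'
#' @param x Path to a Newick file, or a Newick string.
#' @return An ape `phylo` tree.
#' @export
readGuideTree <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("Newick parse error in ", substr(x, 1, 60))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree to Newick
#'
#' @param tree An ape `phylo`.
#' @param path Output path; if NULL the Newick string is returned.
#' @return The path (invisibly) or the Newick string.
#' @export
writeGuideTree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param alignment A [BarcodeAlignment-class].
#' @param path Output path.
#' @export
writeBarcodeFasta <- function(alignment, path) {
  Biostrings::writeXStringSet(alignment@seqs, path, width = 80L)
  invisible(path)
}

#' Write a per-specimen OTU table
#'
#' One row per specimen (stable input order): specimen id, one OTU-id column
#' per method partition, and, when a consensus/resolution result is supplied,
#' the comparison-unit category and final OTU id.
#'
#' @param partitions A [Partition-class] or list of them over identical
#'   specimen sets.
#' @param path Output TSV path, or NULL to just return the table.
#' @param resolution Optional [ResolutionResult-class] supplying `category`
#'   and `final` columns.
#' @return The table, invisibly when written.
#' @export
writeOtuTable <- function(partitions, path = NULL, resolution = NULL) {
  if (is(partitions, "Partition")) partitions <- list(partitions)
  ids <- specimenIds(partitions[[1L]])
  for (p in partitions[-1L]) {
    dif <- c(setdiff(ids, specimenIds(p)), setdiff(specimenIds(p), ids))
    if (length(dif))
      stop("inconsistent specimen sets across partitions: ",
           paste(dif, collapse = ", "))
  }
  tab <- data.frame(specimen_id = ids, stringsAsFactors = FALSE)
  for (p in partitions)
    tab[[methodTag(p)]] <- .membershipFor(p, ids)
  if (!is.null(resolution)) {
    rep <- resolution@report
    unitCat <- rep(NA_character_, length(ids))
    for (i in seq_along(rep@units)) {
      u <- rep@units[[i]]
      unitCat[match(u$members, ids)] <- u$category
    }
    tab$category <- unitCat
    tab$final <- .membershipFor(resolution@partition, ids)
  }
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
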