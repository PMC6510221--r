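#' Read an OTU count table
#'
#' Tab-separated matrix with row ids in the first column and column ids in the
#' header. Amplicon exports usually place taxa on rows; `orientation =
#' "samples_rows"` accepts the transpose and flips it, so the returned matrix
#' is always taxa x samples.
#'
#' @param path TSV file.
#' @param orientation `"taxa_rows"` (default) or `"samples_rows"`.
#' @return integer-valued matrix, taxa x samples.
#' @export
readOtuTable <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) stop("duplicated row ids in ", path)
  if (anyDuplicated(colnames(raw)[-1])) stop("duplicated column ids in ", path)
  body <- raw[, -1, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1))))
    stop("non-numeric cells in ", path)
  m <- as.matrix(body)
  rownames(m) <- ids
  if (anyNA(m) || any(m < 0)) stop("negative or missing counts in ", path)
  if (any(m != round(m))) stop("non-integer counts in ", path)
  if (orientation == "samples_rows") m <- t(m)
  m
}

#' Read a rooted newick tree
#'
#' Parses newick via [ape::read.tree()]. Branches without a stated length are
#' set to 0 with a warning; `strict = TRUE` rejects them instead.
#'
#' @param path newick file.
#' @param strict reject missing branch lengths instead of zero-filling.
#' @return an `ape::phylo`.
#' @export
readTree <- function(path, strict = FALSE) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("unparseable newick in ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("unparseable newick in ", path)
  tr$tip.label <- trimws(tr$tip.label)
  if (is.null(tr$edge.length)) {
    if (strict) stop("tree in ", path, " has no branch lengths")
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    if (strict) stop("tree in ", path, " has branches without lengths")
    warning(sum(is.na(tr$edge.length)), " branch(es) without length set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' Read a sample metadata table
#'
#' TSV with a `sample_id` column, a `group` column (site label) and any number
#' of numeric environmental variables (pH, SOC, TC, TN, TS, NO3-N, NH4-N,
#' NO2-N, ...). Empty cells become `NA` and are excluded pairwise downstream.
#'
#' @param path TSV file.
#' @param sample_col,group_col column names holding ids and site labels.
#' @return data.frame with rownames = sample ids, a `group` column, and the
#'   numeric variables.
#' @export
readSampleMetadata <- function(path, sample_col = "sample_id", group_col = "group") {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (!sample_col %in% colnames(raw)) stop("missing '", sample_col, "' column")
  if (!group_col %in% colnames(raw)) stop("missing '", group_col, "' column")
  ids <- trimws(as.character(raw[[sample_col]]))
  if (anyDuplicated(ids)) stop("duplicated sample ids in ", path)
  grp <- as.character(raw[[group_col]])
  if (any(is.na(grp) | grp == "")) stop("empty group labels in ", path)
  vars <- raw[, setdiff(colnames(raw), c(sample_col, group_col)), drop = FALSE]
  vars[] <- lapply(vars, function(v) suppressWarnings(as.numeric(v)))
  out <- data.frame(group = grp, vars, row.names = ids, check.names = FALSE)
  out
}

#' Build an AssemblyExperiment from files
#'
#' Convenience reader combining [readOtuTable()], [readTree()] and
#' [readSampleMetadata()].
#'
#' @param table_path OTU table TSV.
#' @param tree_path newick file or `NULL`.
#' @param metadata_path metadata TSV or `NULL`.
#' @param orientation passed to [readOtuTable()].
#' @return an [AssemblyExperiment-class].
#' @export
readAssemblyExperiment <- function(table_path, tree_path = NULL,
                                   metadata_path = NULL,
                                   orientation = "taxa_rows") {
  counts <- readOtuTable(table_path, orientation)
  tree <- if (!is.null(tree_path)) readTree(tree_path) else NULL
  meta <- if (!is.null(metadata_path)) readSampleMetadata(metadata_path) else NULL
  AssemblyExperiment(counts, metadata = meta, tree = tree)
}

#' Rarefy a count matrix to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples with fewer than `depth` reads are
#' dropped with a warning, not padded.
#'
#' @param counts taxa x samples integer matrix.
#' @param depth target reads per sample; the study convention is 4020.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return rarefied matrix whose retained columns each sum to `depth`.
#' @export
rarefyCounts <- function(counts, depth = 4020, seed = NULL) {
  counts <- .check_counts(counts)
  if (any(counts != round(counts))) stop("counts must be integers")
  if (depth < 1) stop("depth must be >= 1")
  tot <- colSums(counts)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[!keep], collapse = ", "))
  .with_seed(seed, {
    out <- vapply(which(keep), function(s) {
      x <- counts[, s]
      if (sum(x) == depth) return(x)
      reads <- rep.int(seq_along(x), x)
      tabulate(sample(reads, depth), nbins = length(x))
    }, numeric(nrow(counts)))
  })
  dimnames(out) <- list(rownames(counts), colnames(counts)[keep])
  out
}

#' @describeIn rarefyCounts method for AssemblyExperiment: rarefies the count
#'   assay and subsets samples accordingly.
#' @param x an [AssemblyExperiment-class].
#' @export
setGeneric("rarefy", function(x, depth = 4020, seed = NULL) standardGeneric("rarefy"))

#' @rdname rarefyCounts
#' @export
setMethod("rarefy", "AssemblyExperiment", function(x, depth = 4020, seed = NULL) {
  rc <- rarefyCounts(otuCounts(x), depth = depth, seed = seed)
  x <- x[, colnames(rc)]
  SummarizedExperiment::assay(x, "counts") <- rc
  validObject(x)
  x
})

#' Write a long-format result table
#'
#' TSV with header, no quoting, no rownames; round-trips through
#' `read.delim`.
#'
#' @param records non-empty data.frame.
#' @param path output file.
#' @export
writeLongTable <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("refusing to write an empty table")
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a square distance-style matrix
#'
#' `writeDistanceMatrix` stores ids in the first column and header;
#' `readDistanceMatrix` restores the symmetric matrix within 1e-12.
#'
#' @param m symmetric matrix with dimnames.
#' @param path TSV file.
#' @return `readDistanceMatrix` returns the matrix.
#' @export
writeDistanceMatrix <- function(m, path) {
  m <- .check_dist_matrix(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  raw <- read.delim(path, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- as.character(raw[[1]])
  .check_dist_matrix(m)
}
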