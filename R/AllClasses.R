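#' @import methods
#' @importFrom stats cor sd var setNames rmultinom rnorm rlnorm runif pt lm coef
#' @importFrom utils combn read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

setOldClass("phylo")
setOldClass("igraph")
setClassUnion("phyloOrNULL", members = c("phylo", "NULL"))

#' Container for an OTU table, sample metadata and a phylogeny
#'
#' `AssemblyExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with a rooted phylogenetic tree whose tips cover the taxa of the count
#' assay. Rows are taxa (OTUs), columns are samples; the single assay
#' `"counts"` holds non-negative integer read counts. Sample metadata
#' (site/group labels and environmental covariates such as pH or SOC) live in
#' `colData`.
#'
#' @slot tree a rooted `ape::phylo` tree with branch lengths, or `NULL` when
#'   no phylogeny is attached (taxonomic analyses only).
#'
#' @seealso [AssemblyExperiment()] for construction, [otuCounts()],
#'   [phyloTree()], [sampleGroups()] for access.
#' @export
setClass("AssemblyExperiment",
  contains = "SummarizedExperiment",
  representation(tree = "phyloOrNULL")
)

setValidity("AssemblyExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(m) || any(m < 0)) msg <- c(msg, "counts must be non-negative and complete")
    if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "taxon ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!is.null(object@tree)) {
    missing <- setdiff(rownames(object), object@tree$tip.label)
    if (length(missing))
      msg <- c(msg, paste0(length(missing), " taxa absent from tree tips (e.g. '",
                           missing[1], "')"))
    if (is.null(object@tree$edge.length))
      msg <- c(msg, "tree must carry branch lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AssemblyExperiment
#'
#' Assembles counts, metadata and tree into a validated container. The tree is
#' pruned to the taxa of the table (extra tips are dropped); taxa missing from
#' the tree are an error. Metadata rows are matched to samples by name.
#'
#' @param counts numeric matrix of non-negative integers, taxa x samples, with
#'   unique dimnames.
#' @param metadata `data.frame`/`DataFrame` of per-sample variables, rownames
#'   (or a `sample_id` column) matching `colnames(counts)`. A `group` column
#'   carries the site label. May be `NULL`.
#' @param tree rooted `phylo` with branch lengths, or `NULL`.
#' @return An [AssemblyExperiment-class] object.
#' @examples
#' counts <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
#'                  dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
#' ae <- AssemblyExperiment(counts)
#' otuCounts(ae)
#' @export
AssemblyExperiment <- function(counts, metadata = NULL, tree = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (is.null(rownames(metadata)) || all(rownames(metadata) == seq_len(nrow(metadata)))) {
      if ("sample_id" %in% colnames(metadata))
        rownames(metadata) <- metadata$sample_id
    }
    absent <- setdiff(colnames(counts), rownames(metadata))
    if (length(absent))
      stop("metadata missing samples: ", paste(absent, collapse = ", "))
    metadata <- metadata[colnames(counts), , drop = FALSE]
    metadata <- S4Vectors::DataFrame(metadata)
  } else {
    metadata <- S4Vectors::DataFrame(row.names = colnames(counts))
  }
  if (!is.null(tree)) {
    extra <- setdiff(tree$tip.label, rownames(counts))
    if (length(extra)) tree <- ape::keep.tip(tree, intersect(tree$tip.label, rownames(counts)))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = metadata)
  new("AssemblyExperiment", se, tree = tree)
}

#' Accessors for AssemblyExperiment
#'
#' `otuCounts` returns the taxa x samples count matrix, `phyloTree` the
#' attached phylogeny (or `NULL`), `sampleGroups` the per-sample site labels
#' (named character vector from the `group` column of `colData`).
#'
#' @param x an [AssemblyExperiment-class].
#' @return See the per-accessor description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setMethod("otuCounts", "AssemblyExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @rdname accessors
#' @export
setMethod("phyloTree", "AssemblyExperiment", function(x) x@tree)

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "AssemblyExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% colnames(cd))
    stop("no 'group' column in colData")
  setNames(as.character(cd$group), rownames(cd))
})

setMethod("show", "AssemblyExperiment", function(object) {
  cat("AssemblyExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  if ("group" %in% colnames(cd)) {
    tab <- table(cd$group)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(object@tree))
    cat("  tree:", length(object@tree$tip.label), "tips, rooted =",
        ape::is.rooted(object@tree), "\n")
  vars <- setdiff(colnames(cd), "group")
  if (length(vars)) cat("  variables:", paste(vars, collapse = ", "), "\n")
  invisible(NULL)
})

#' Thresholded co-occurrence network of OTUs
#'
#' Holds the graph built from a screened Spearman edge list together with its
#' node table (degree, betweenness, module, Zi, Pi, role), edge table (rho,
#' sign, adjusted p) and a topology summary block.
#'
#' @slot graph an `igraph` undirected graph; edge attribute `rho`, `sign`.
#' @slot nodes `data.frame` of per-node attributes.
#' @slot edges `data.frame`, one row per unordered taxon pair kept.
#' @slot topology named `list`: n_vertices, n_edges, avg_degree, modularity,
#'   n_modules, avg_clustering, avg_path_length, betweenness_centralization.
#' @export
setClass("CooccurrenceNetwork",
  representation(graph = "igraph", nodes = "data.frame",
                 edges = "data.frame", topology = "list")
)

setValidity("CooccurrenceNetwork", function(object) {
  g <- object@graph
  if (igraph::any_loop(g)) return("self-loops are not allowed")
  if (igraph::any_multiple(g)) return("duplicate edges are not allowed")
  TRUE
})

setMethod("show", "CooccurrenceNetwork", function(object) {
  tp <- object@topology
  cat("CooccurrenceNetwork:", tp$n_vertices, "vertices,", tp$n_edges, "edges\n")
  if (!is.null(tp$modularity) && !is.na(tp$modularity))
    cat(sprintf("  modularity %.3f over %d modules; avg degree %.2f; avg clustering %.3f\n",
                tp$modularity, tp$n_modules, tp$avg_degree, tp$avg_clustering))
  if ("role" %in% colnames(object@nodes)) {
    tab <- table(object@nodes$role)
    cat("  roles:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' @rdname networkAccessors
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' Accessors for CooccurrenceNetwork
#'
#' `networkGraph` returns the underlying igraph object, `networkNodes` and
#' `networkEdges` the node/edge tables, `networkTopology` the topology block.
#'
#' @param x a [CooccurrenceNetwork-class].
#' @return igraph / data.frame / list respectively.
#' @name networkAccessors
#' @export
setMethod("networkGraph", "CooccurrenceNetwork", function(x) x@graph)

#' @rdname networkAccessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname networkAccessors
#' @export
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)

#' @rdname networkAccessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname networkAccessors
#' @export
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)

#' @rdname networkAccessors
#' @export
setGeneric("networkTopology", function(x) standardGeneric("networkTopology"))

#' @rdname networkAccessors
#' @export
setMethod("networkTopology", "CooccurrenceNetwork", function(x) x@topology)
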