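#' Alpha-diversity estimators
#'
#' Per-sample richness, richness estimators, entropy indices, Faith's
#' phylogenetic diversity and Good's coverage, the set usually reported for
#' rarefied 16S OTU tables. All take one sample's count vector;
#' [alphaDiversity()] applies them across a table.
#'
#' @param x non-negative count vector (integers where the estimator's
#'   singleton/doubleton definition requires them).
#' @name alpha-estimators
NULL

.check_vec <- function(x, integer = FALSE) {
  if (length(x) == 0) stop("empty count vector")
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative and complete")
  if (integer && any(x != round(x))) stop("counts must be integers")
  x
}

#' @describeIn alpha-estimators observed richness: number of taxa with
#'   positive count.
#' @export
observedRichness <- function(x) {
  x <- .check_vec(x)
  sum(x > 0)
}

#' @describeIn alpha-estimators bias-corrected Chao1,
#'   \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} with \eqn{F_1,F_2} the singleton
#'   and doubleton counts.
#' @export
chao1 <- function(x) {
  x <- .check_vec(x, integer = TRUE)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @describeIn alpha-estimators ACE with abundance threshold
#'   `rare_threshold` (default 10). When every rare taxon is a singleton the
#'   sample-coverage term is 0 and the estimator is undefined; Chao1 is
#'   returned instead with a warning.
#' @param rare_threshold count at or below which a taxon belongs to the rare
#'   class.
#' @export
aceEstimate <- function(x, rare_threshold = 10) {
  x <- .check_vec(x, integer = TRUE)
  pos <- x[x > 0]
  rare <- pos[pos <= rare_threshold]
  s_abund <- sum(pos > rare_threshold)
  s_rare <- length(rare)
  if (s_rare == 0) return(as.numeric(s_abund))
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) {
    warning("all rare taxa are singletons; ACE undefined, returning Chao1")
    return(chao1(x))
  }
  fk <- tabulate(rare, nbins = rare_threshold)
  g2 <- s_rare / c_ace * sum(seq_len(rare_threshold) * (seq_len(rare_threshold) - 1) * fk) /
    (n_rare * (n_rare - 1)) - 1
  g2 <- max(g2, 0)
  if (!is.finite(g2)) g2 <- 0   # n_rare == 1
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

#' @describeIn alpha-estimators Shannon entropy \eqn{-\sum p_i \log p_i};
#'   natural log by default, mirroring mothur's summary convention.
#' @param base logarithm base.
#' @export
shannonIndex <- function(x, base = exp(1)) {
  x <- .check_vec(x)
  if (sum(x) == 0) stop("all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}

#' @describeIn alpha-estimators Simpson index. `"gini"` (default) is the
#'   Gini--Simpson diversity \eqn{1-\sum p_i^2}; `"dominance"` is
#'   \eqn{\sum p_i^2}.
#' @param variant which Simpson form to return.
#' @export
simpsonIndex <- function(x, variant = c("gini", "dominance")) {
  variant <- match.arg(variant)
  x <- .check_vec(x)
  if (sum(x) == 0) stop("all-zero sample")
  p <- x / sum(x)
  d <- sum(p^2)
  if (variant == "gini") 1 - d else d
}

#' @describeIn alpha-estimators Faith's phylogenetic diversity: total branch
#'   length of the union of root-to-tip paths of the taxa present
#'   (root-inclusive). Delegates to [picante::pd()].
#' @param tree rooted `phylo`; `names(x)` must match its tip labels.
#' @export
faithPD <- function(x, tree) {
  x <- .check_vec(x)
  if (is.null(names(x))) stop("count vector must carry taxon names")
  present <- names(x)[x > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing))
    stop("taxa absent from tree: ", paste(missing, collapse = ", "))
  comm <- matrix(as.numeric(x > 0), nrow = 1, dimnames = list("s", names(x)))
  picante::pd(comm, tree, include.root = TRUE)$PD
}

#' @describeIn alpha-estimators Good's coverage \eqn{1 - F_1/N}: the
#'   estimated fraction of the community represented by the sampled reads.
#' @export
goodsCoverage <- function(x) {
  x <- .check_vec(x, integer = TRUE)
  n <- sum(x)
  if (n == 0) stop("zero total reads")
  1 - sum(x == 1) / n
}

#' Alpha-diversity table for every sample
#'
#' Applies the estimators of [alpha-estimators] column-wise. Coverage and the
#' richness estimators are computed on the table as given; whether that table
#' is rarefied first is the caller's choice.
#'
#' @param x taxa x samples count matrix or an [AssemblyExperiment-class].
#' @param tree rooted `phylo` for Faith's PD; taken from the object when `x`
#'   is an AssemblyExperiment. `NULL` skips the PD column.
#' @return data.frame with one row per sample: `sample_id`, `sobs`, `chao1`,
#'   `ace`, `shannon`, `simpson`, `faith_pd`, `goods_coverage`.
#' @export
alphaDiversity <- function(x, tree = NULL) {
  if (is(x, "AssemblyExperiment")) {
    if (is.null(tree)) tree <- phyloTree(x)
    x <- otuCounts(x)
  }
  counts <- .check_counts(x)
  out <- data.frame(
    sample_id = colnames(counts),
    sobs = apply(counts, 2, observedRichness),
    chao1 = apply(counts, 2, chao1),
    ace = apply(counts, 2, aceEstimate),
    shannon = apply(counts, 2, shannonIndex),
    simpson = apply(counts, 2, simpsonIndex),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(tree)) {
    comm <- t(counts > 0) * 1
    out$faith_pd <- picante::pd(comm, tree, include.root = TRUE)$PD
  } else out$faith_pd <- NA_real_
  out$goods_coverage <- apply(counts, 2, goodsCoverage)
  out
}
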