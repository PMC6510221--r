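#' Cophenetic (tip-to-tip) distance matrix
#'
#' Path-length distances between every pair of tips, via
#' [ape::cophenetic.phylo()]. Negative branch lengths are rejected.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix with zero diagonal, tips as dimnames.
#' @export
copheneticMatrix <- function(tree) {
  if (length(tree$tip.label) < 2) stop("need a tree with at least 2 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  stats::cophenetic(tree)
}

#' Abundance-weighted beta mean-nearest-taxon distance (betaMNTD)
#'
#' For each taxon in one community, the phylogenetic distance to its nearest
#' taxon in the other community (0 when the taxon itself is present in both),
#' averaged with relative-abundance weights and symmetrized:
#' \deqn{\beta MNTD = \tfrac12\left[\sum_{i} f_i \min_j d_{ij} +
#'   \sum_{j} g_j \min_i d_{ji}\right]}
#' with \eqn{f}, \eqn{g} the within-community relative abundances (uniform
#' over present taxa when `abundance_weighted = FALSE`).
#'
#' @param x,y count or abundance vectors over the same taxa, named or aligned
#'   with `d`'s ids; non-empty supports.
#' @param d cophenetic matrix from [copheneticMatrix()].
#' @param abundance_weighted weight by relative abundance (the study setting)
#'   or uniformly over present taxa. In the unweighted form the two
#'   communities contribute equally (the mean of the two community means);
#'   implementations that pool taxa across both communities differ when
#'   richness is unbalanced.
#' @return non-negative scalar; 0 for compositionally identical communities.
#' @export
betaMNTD <- function(x, y, d, abundance_weighted = TRUE) {
  d <- .check_dist_matrix(d, "cophenetic matrix")
  if (is.null(names(x)) || is.null(names(y)))
    stop("count vectors must carry taxon names")
  if (!identical(names(x), names(y))) stop("x and y must cover the same taxa")
  missing <- setdiff(names(x)[x > 0 | y > 0], rownames(d))
  if (length(missing)) stop("taxa absent from distance matrix: ",
                            paste(missing, collapse = ", "))
  m <- betaMNTDMatrix(cbind(a = x, b = y), d, abundance_weighted)
  m["a", "b"]
}

#' betaMNTD over all sample pairs
#'
#' @param counts taxa x samples matrix (taxa named as in `d`).
#' @param d cophenetic matrix covering all table taxa.
#' @inheritParams betaMNTD
#' @return symmetric samples x samples matrix.
#' @export
betaMNTDMatrix <- function(counts, d, abundance_weighted = TRUE) {
  counts <- .check_counts(counts)
  if (any(colSums(counts) == 0)) stop("sample with empty support")
  missing <- setdiff(rownames(counts), rownames(d))
  if (length(missing)) stop("taxa absent from distance matrix: ",
                            paste(missing, collapse = ", "))
  d <- d[rownames(counts), rownames(counts), drop = FALSE]
  P <- if (abundance_weighted) relativeAbundance(counts)
       else relativeAbundance((counts > 0) * 1)
  # M[t, s]: distance from taxon t to its nearest taxon present in sample s
  M <- vapply(seq_len(ncol(counts)), function(s) {
    supp <- which(counts[, s] > 0)
    if (length(supp) == 1) d[supp, ] else
      apply(d[supp, , drop = FALSE], 2, min)
  }, numeric(nrow(counts)))
  A <- crossprod(P, M)                      # A[a, b] = sum_t P[t,a] * M[t,b]
  out <- 0.5 * (A + t(A))
  diag(out) <- 0
  dimnames(out) <- list(colnames(counts), colnames(counts))
  out
}

#' beta nearest-taxon index (betaNTI) via the tip-shuffle null
#'
#' Quantifies phylogenetic turnover between communities relative to a null in
#' which taxon identities are shuffled across the tips of the phylogeny
#' (equivalently, rows and columns of the cophenetic matrix are permuted
#' jointly), holding community compositions fixed. Per sample pair,
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \overline{\beta MNTD}_{null}) /
#'   sd(\beta MNTD_{null}).}
#' One shuffle is shared by all pairs within a rep. |betaNTI| > 2 indicates
#' selection: variable (> +2, communities more phylogenetically divergent
#' than the null) or homogeneous (< -2).
#'
#' @param counts taxa x samples matrix, or an [AssemblyExperiment-class]
#'   carrying a tree.
#' @param tree rooted `phylo` covering all table taxa (ignored when `counts`
#'   is an AssemblyExperiment).
#' @param reps number of shuffles (default 999). With `method =
#'   "exhaustive"` every permutation of the tips is evaluated instead
#'   (feasible for at most 7 taxa) and `reps` is ignored.
#' @param seed optional integer seed.
#' @param abundance_weighted passed to [betaMNTDMatrix()].
#' @param method `"sample"` (Monte-Carlo shuffles) or `"exhaustive"`.
#' @return data.frame per pair: `sample_i`, `sample_j`, `bmntd_observed`,
#'   `bmntd_null_mean`, `bmntd_null_sd`, `bnti`. Pairs whose null sd is 0
#'   (shuffle-invariant geometry, e.g. an equal-branch star tree) get
#'   `bnti = NA` rather than a silent 0; the count is reported via a warning.
#' @export
betaNTI <- function(counts, tree = NULL, reps = 999, seed = NULL,
                    abundance_weighted = TRUE,
                    method = c("sample", "exhaustive")) {
  method <- match.arg(method)
  if (is(counts, "AssemblyExperiment")) {
    tree <- phyloTree(counts)
    counts <- otuCounts(counts)
  }
  if (is.null(tree)) stop("a tree is required")
  counts <- .check_counts(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  d <- copheneticMatrix(tree)
  missing <- setdiff(rownames(counts), rownames(d))
  if (length(missing)) stop("taxa absent from tree: ",
                            paste(missing, collapse = ", "))
  d <- d[rownames(counts), rownames(counts)]
  obs <- .upper_vec(betaMNTDMatrix(counts, d, abundance_weighted))
  n_taxa <- nrow(counts)
  shuffles <- if (method == "exhaustive") {
    if (n_taxa > 7) stop("exhaustive enumeration limited to 7 taxa")
    perms <- .all_permutations(n_taxa)
    lapply(seq_len(nrow(perms)), function(i) perms[i, ])
  } else {
    if (reps < 2) stop("need reps >= 2 for a defined null sd")
    .with_seed(seed, replicate(reps, sample.int(n_taxa), simplify = FALSE))
  }
  np <- length(obs)
  sum1 <- numeric(np); sum2 <- numeric(np)
  for (perm in shuffles) {
    dp <- d[perm, perm]
    dimnames(dp) <- dimnames(d)
    b <- .upper_vec(betaMNTDMatrix(counts, dp, abundance_weighted))
    sum1 <- sum1 + b
    sum2 <- sum2 + b^2
  }
  k <- length(shuffles)
  mu <- sum1 / k
  sdv <- sqrt(pmax(sum2 - k * mu^2, 0) / (k - 1))
  out <- .pair_index(colnames(counts))
  out$bmntd_observed <- obs
  out$bmntd_null_mean <- mu
  out$bmntd_null_sd <- sdv
  out$bnti <- ifelse(sdv > 1e-12, (obs - mu) / sdv, NA_real_)
  n_undef <- sum(is.na(out$bnti))
  if (n_undef > 0)
    warning(n_undef, " pair(s) have zero null sd; betaNTI flagged NA")
  out
}
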