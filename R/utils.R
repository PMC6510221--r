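# internal helpers shared across modules

.check_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative and complete")
  counts
}

#' Relative-abundance view of a count matrix
#'
#' Columns with positive totals sum to 1; all-zero columns stay zero.
#'
#' @param counts taxa x samples matrix of non-negative counts.
#' @return matrix of per-sample relative abundances.
#' @export
relativeAbundance <- function(counts) {
  counts <- .check_counts(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, "/")
}

# symmetric matrix with zero diagonal and shared ids, else error
.check_dist_matrix <- function(m, name = "matrix", tol = 1e-12) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop(name, " must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop(name, " must carry identical row and column ids")
  if (max(abs(m - t(m))) > tol) stop(name, " must be symmetric")
  if (max(abs(diag(m))) > tol) stop(name, " must have a zero diagonal")
  m
}

# upper triangle (i < j) as a vector, pair order fixed by combn over ids
.upper_vec <- function(m) m[upper.tri(m)]

# long pair index for n samples, matching upper.tri column-major order
.pair_index <- function(ids) {
  n <- length(ids)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(sample_i = ids[idx[, 1]], sample_j = ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

# all permutations of seq_len(n); guarded, enumeration oracles only
.all_permutations <- function(n) {
  if (n > 8) stop("refusing to enumerate permutations for n > 8")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# turn a long pairwise statistic into a symmetric matrix over ids
#' Reshape a pairwise result column into a distance-style matrix
#'
#' Builds the symmetric samples x samples matrix (zero diagonal) from a long
#' pairwise table such as the output of [betaNTI()] or [nullDeviation()].
#'
#' @param pairs data.frame with `sample_i`, `sample_j` columns.
#' @param value name of the column to spread.
#' @param ids optional id order; defaults to ids seen in the table.
#' @return symmetric numeric matrix with dimnames.
#' @export
pairwiseToMatrix <- function(pairs, value, ids = NULL) {
  stopifnot(all(c("sample_i", "sample_j", value) %in% colnames(pairs)))
  if (is.null(ids)) ids <- unique(c(pairs$sample_i, pairs$sample_j))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  i <- match(pairs$sample_i, ids); j <- match(pairs$sample_j, ids)
  if (anyNA(i) || anyNA(j)) stop("pair ids absent from 'ids'")
  m[cbind(i, j)] <- pairs[[value]]
  m[cbind(j, i)] <- pairs[[value]]
  m
}

# seeded evaluation: leaves caller RNG untouched when seed is NULL
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
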