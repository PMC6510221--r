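#' Bray--Curtis dissimilarity
#'
#' \eqn{1 - 2\sum_i \min(x_i,y_i) / (\sum x + \sum y)}, bounded in [0, 1].
#' Matrix-wide computation goes through [vegan::vegdist()]; this scalar form
#' exists for clarity and the null-model inner loop.
#'
#' @param x,y equal-length non-negative count (or abundance) vectors; at
#'   least one total must be positive.
#' @return dissimilarity in `[0, 1]`.
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both samples empty: Bray-Curtis undefined")
  1 - 2 * sum(pmin(x, y)) / tot
}

#' Bray--Curtis matrix over all sample pairs
#'
#' @param counts taxa x samples matrix.
#' @return symmetric samples x samples matrix.
#' @export
brayCurtisMatrix <- function(counts) {
  counts <- .check_counts(counts)
  if (any(colSums(counts) == 0)) stop("sample with zero total reads")
  as.matrix(vegan::vegdist(t(counts), method = "bray"))
}

#' Regional-pool statistics for null assembly
#'
#' Occurrence frequency (number of samples a taxon occurs in) drives which
#' taxa enter a null community; mean relative abundance across samples drives
#' how the reads are distributed among them. `uniform` weighting flattens
#' both, for sensitivity analysis.
#'
#' @param counts taxa x samples matrix defining the pool (pass one site at a
#'   time for within-site nulls).
#' @param weighting `"occurrence_frequency"` (default) or `"uniform"`.
#' @return list with numeric vectors `freq` and `mra`, named by taxon.
#' @export
poolStatistics <- function(counts, weighting = c("occurrence_frequency", "uniform")) {
  weighting <- match.arg(weighting)
  counts <- .check_counts(counts)
  occ <- rowSums(counts > 0)
  if (weighting == "uniform") {
    freq <- as.numeric(occ > 0)
    mra <- as.numeric(occ > 0)
  } else {
    freq <- occ
    mra <- rowMeans(relativeAbundance(counts))
  }
  list(freq = setNames(freq, rownames(counts)),
       mra = setNames(mra, rownames(counts)))
}

#' Assemble one null community
#'
#' Richness- and abundance-preserving randomization: (i) draw `richness`
#' distinct taxa without replacement with probability proportional to
#' occurrence frequency; (ii) seed each with one individual; (iii) place the
#' remaining `total - richness` individuals multinomially with probability
#' proportional to the selected taxa's mean relative abundance.
#'
#' @param richness number of taxa the null community must contain.
#' @param total number of individuals (reads) it must contain.
#' @param pool list as returned by [poolStatistics()].
#' @param seed optional integer seed.
#' @return count vector over all pool taxa with exactly `richness` positive
#'   entries summing to `total`.
#' @export
assembleNullCommunity <- function(richness, total, pool, seed = NULL) {
  freq <- pool$freq; mra <- pool$mra
  avail <- which(freq > 0)
  if (richness < 1 || richness > length(avail))
    stop("richness infeasible for this pool")
  if (total < richness) stop("total must be at least richness")
  .with_seed(seed, {
    chosen <- if (length(avail) == 1) avail else
      avail[sample.int(length(avail), richness, prob = freq[avail])]
    out <- numeric(length(freq))
    out[chosen] <- 1
    extra <- total - richness
    if (extra > 0) {
      w <- mra[chosen]
      if (sum(w) <= 0) w <- rep(1, length(chosen))
      out[chosen] <- out[chosen] + as.numeric(rmultinom(1, extra, prob = w))
    }
  })
  names(out) <- names(freq)
  out
}

# one null table: every sample re-assembled preserving its richness and total
.null_table <- function(counts, pool) {
  null <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    null[, s] <- assembleNullCommunity(sum(counts[, s] > 0), sum(counts[, s]), pool)
  }
  null
}

#' Beta-diversity null deviation per sample pair
#'
#' For every sample pair, the observed Bray--Curtis dissimilarity is compared
#' against its distribution over `reps` null tables in which each sample is
#' re-assembled by [assembleNullCommunity()], preserving its own richness and
#' total abundance. Values near zero indicate chance expectation; large
#' positive (or negative) deviations indicate communities less (more) similar
#' than expected by chance, i.e. deterministic structuring.
#'
#' @param counts taxa x samples matrix; the samples passed define the
#'   regional pool (pass one site at a time for within-site values).
#' @param reps null iterations; 999 is the study convention.
#' @param seed optional integer seed.
#' @param weighting passed to [poolStatistics()].
#' @return data.frame per pair: `sample_i`, `sample_j`, `bc_observed`,
#'   `bc_null_mean`, `bc_null_sd`, `null_deviation` (obs - null mean) and
#'   `relative_null_deviation` ((obs - null mean)/null mean; `NA` when the
#'   null mean is 0).
#' @export
nullDeviation <- function(counts, reps = 999, seed = NULL,
                          weighting = "occurrence_frequency") {
  counts <- .check_counts(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with zero total reads")
  if (reps < 1) stop("reps must be >= 1")
  pool <- poolStatistics(counts, weighting)
  obs <- brayCurtisMatrix(counts)
  np <- ncol(counts) * (ncol(counts) - 1) / 2
  sum1 <- numeric(np); sum2 <- numeric(np)
  .with_seed(seed, {
    for (r in seq_len(reps)) {
      bc <- .upper_vec(brayCurtisMatrix(.null_table(counts, pool)))
      sum1 <- sum1 + bc
      sum2 <- sum2 + bc^2
    }
  })
  mu <- sum1 / reps
  sdv <- if (reps > 1) sqrt(pmax(sum2 - reps * mu^2, 0) / (reps - 1)) else rep(0, np)
  out <- .pair_index(colnames(counts))
  out$bc_observed <- .upper_vec(obs)
  out$bc_null_mean <- mu
  out$bc_null_sd <- sdv
  out$null_deviation <- out$bc_observed - mu
  out$relative_null_deviation <- ifelse(mu > 0, out$null_deviation / mu, NA_real_)
  out
}

#' Per-site summary of null deviations
#'
#' Averages a deviation statistic over within-site pairs; between-site pairs
#' are excluded. Groups with fewer than 2 samples are skipped with a warning.
#'
#' @param results output of [nullDeviation()] (run per site or pooled; only
#'   within-group pairs are used either way).
#' @param groups named character vector mapping sample id to site label, as
#'   from [sampleGroups()].
#' @param statistic `"relative_null_deviation"` (the study's headline form)
#'   or `"null_deviation"`.
#' @return data.frame per group: `group`, `mean`, `sd`, `n_pairs`.
#' @export
siteNullDeviationSummary <- function(results, groups,
                                     statistic = c("relative_null_deviation",
                                                   "null_deviation")) {
  statistic <- match.arg(statistic)
  gi <- groups[results$sample_i]; gj <- groups[results$sample_j]
  if (anyNA(gi) || anyNA(gj)) stop("samples missing from 'groups'")
  within <- results[gi == gj, , drop = FALSE]
  within$group <- groups[within$sample_i]
  small <- setdiff(unique(groups), unique(within$group))
  if (length(small))
    warning("group(s) with < 2 samples skipped: ", paste(small, collapse = ", "))
  out <- do.call(rbind, lapply(split(within, within$group), function(d)
    data.frame(group = d$group[1], mean = mean(d[[statistic]]),
               sd = if (nrow(d) > 1) sd(d[[statistic]]) else 0,
               n_pairs = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
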