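#' Process labels
#'
#' The five-way partition of the (betaNTI, RC_bray) plane used to attribute
#' community turnover to assembly processes.
#'
#' @format character vector of the level names, in reporting order.
#' @export
processLevels <- c("variable_selection", "homogeneous_selection",
                   "dispersal_limitation", "homogenizing_dispersal",
                   "undominated")

#' Classify sample pairs into assembly processes
#'
#' Strict thresholds: betaNTI > +2 -> variable selection; betaNTI < -2 ->
#' homogeneous selection; |betaNTI| < 2 with RC_bray > +0.95 -> dispersal
#' limitation; |betaNTI| < 2 with RC_bray < -0.95 -> homogenizing dispersal;
#' anything else (including exact boundary values) -> undominated.
#'
#' @param bnti numeric vector of betaNTI values (no NAs; exclude undefined
#'   pairs upstream).
#' @param rc numeric vector of RC_bray values in `[-1, 1]`.
#' @return factor with levels [processLevels], same length as the inputs.
#' @export
classifyPair <- function(bnti, rc) {
  if (length(bnti) != length(rc)) stop("inputs differ in length")
  if (anyNA(bnti) || anyNA(rc)) stop("undefined values; exclude them upstream")
  if (any(abs(rc) > 1 + 1e-12)) stop("RC_bray outside [-1, 1]")
  lab <- rep("undominated", length(bnti))
  lab[bnti > 2] <- "variable_selection"
  lab[bnti < -2] <- "homogeneous_selection"
  inside <- abs(bnti) < 2
  lab[inside & rc > 0.95] <- "dispersal_limitation"
  lab[inside & rc < -0.95] <- "homogenizing_dispersal"
  factor(lab, levels = processLevels)
}

#' Join betaNTI and RC_bray pair tables
#'
#' Merges on the unordered sample pair and appends the process label for
#' defined pairs.
#'
#' @param bnti output of [betaNTI()].
#' @param rc output of [raupCrickBray()].
#' @return data.frame with both statistics and a `process` column (`NA` for
#'   pairs with undefined betaNTI).
#' @export
joinPairStatistics <- function(bnti, rc) {
  key <- function(d) paste(pmin(d$sample_i, d$sample_j),
                           pmax(d$sample_i, d$sample_j), sep = "\r")
  m <- match(key(bnti), key(rc))
  if (anyNA(m)) stop("pair sets differ between the two tables")
  out <- bnti
  out$rc_bray <- rc$rc_bray[m]
  out$bc_observed <- rc$bc_observed[m]
  defined <- !is.na(out$bnti)
  out$process <- factor(NA_character_, levels = processLevels)
  out$process[defined] <- classifyPair(out$bnti[defined], out$rc_bray[defined])
  out
}

#' Per-group fractions of assembly processes
#'
#' Label fractions over defined within-group pairs; the count of pairs with
#' undefined betaNTI is reported but never enters a fraction.
#'
#' @param pairs output of [joinPairStatistics()] (columns `sample_i`,
#'   `sample_j`, `process`).
#' @param groups named character vector sample id -> group, or `NULL` to
#'   summarize all pairs as one group `"all"`.
#' @return data.frame per group: `group`, one fraction column per process
#'   level, `n_pairs` (defined) and `n_undefined`.
#' @export
processFractions <- function(pairs, groups = NULL) {
  if (is.null(groups)) {
    pairs$group <- "all"
  } else {
    gi <- groups[pairs$sample_i]; gj <- groups[pairs$sample_j]
    if (anyNA(gi) || anyNA(gj)) stop("samples missing from 'groups'")
    pairs <- pairs[gi == gj, , drop = FALSE]
    pairs$group <- groups[pairs$sample_i]
    if (nrow(pairs) == 0) stop("no within-group pairs")
  }
  out <- do.call(rbind, lapply(split(pairs, pairs$group), function(d) {
    def <- d[!is.na(d$process), , drop = FALSE]
    if (nrow(def) == 0) {
      warning("group '", d$group[1], "' has no defined pairs; skipped")
      return(NULL)
    }
    fr <- as.list(table(def$process) / nrow(def))
    data.frame(group = d$group[1], as.data.frame(fr, check.names = FALSE),
               n_pairs = nrow(def), n_undefined = sum(is.na(d$process)),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise environmental-difference matrix
#'
#' \eqn{|v_i - v_j|} for one metadata variable; samples with a missing value
#' are dropped (pairwise exclusion happens here, at matrix construction).
#'
#' @param meta data.frame as from [readSampleMetadata()] (rownames = sample
#'   ids).
#' @param variable column name.
#' @return symmetric matrix over the samples with non-missing values.
#' @export
envDifferenceMatrix <- function(meta, variable) {
  if (!variable %in% colnames(meta)) stop("variable '", variable, "' not found")
  v <- meta[[variable]]
  names(v) <- rownames(meta)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("variable '", variable, "' is entirely missing")
  m <- abs(outer(v, v, "-"))
  dimnames(m) <- list(names(v), names(v))
  m
}

#' Regression of a pairwise statistic on an environmental distance
#'
#' Ordinary least squares on the vectorized upper triangles of two matched
#' matrices (e.g. betaNTI against |SOC_i - SOC_j|). Because the pairwise
#' observations share samples and are not independent, the headline p-value
#' comes from a Mantel-style permutation of one matrix's sample labels; the
#' parametric t-test p is also returned, labelled naive.
#'
#' @param x,y symmetric matrices over the same samples (same id order).
#' @param permutations label permutations for the p-value (default 999).
#' @param seed optional integer seed.
#' @return list: `slope`, `intercept`, `r`, `r_squared`, `p_permutation`
#'   (two-sided on r), `p_naive`, `n_pairs`.
#' @export
pairwiseRegression <- function(x, y, permutations = 999, seed = NULL) {
  x <- .check_dist_matrix(x, "x"); y <- .check_dist_matrix(y, "y")
  if (!identical(rownames(x), rownames(y))) stop("matrices must share ids")
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples (3 pairs)")
  xv <- .upper_vec(x); yv <- .upper_vec(y)
  if (var(xv) == 0) stop("zero variance in x")
  fit <- lm(yv ~ xv)
  r_obs <- cor(xv, yv)
  .with_seed(seed, {
    exceed <- 0L
    for (p in seq_len(permutations)) {
      perm <- sample.int(n)
      r_perm <- cor(.upper_vec(x[perm, perm]), yv)
      if (abs(r_perm) >= abs(r_obs) - 1e-12) exceed <- exceed + 1L
    }
  })
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r_obs, r_squared = r_obs^2,
       p_permutation = (1 + exceed) / (1 + permutations),
       p_naive = suppressWarnings(summary(fit)$coefficients[2, 4]),
       n_pairs = length(xv))
}

#' Mantel test between two distance-style matrices
#'
#' Pearson correlation of the upper triangles; significance by joint
#' row/column permutation of one matrix's sample labels, one-sided
#' (greater), with the +1 correction:
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\})/(1 + permutations)}.
#' `exact = TRUE` enumerates all `n!` label permutations (n <= 7) and returns
#' the exact permutation p (identity included in the reference set).
#'
#' @param a,b symmetric matrices with identical ids in identical order.
#' @param permutations number of random permutations (default 999).
#' @param seed optional integer seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return list: `r`, `p`, `permutations`.
#' @export
mantelTest <- function(a, b, permutations = 999, seed = NULL, exact = FALSE) {
  a <- .check_dist_matrix(a, "a"); b <- .check_dist_matrix(b, "b")
  if (!identical(rownames(a), rownames(b))) stop("matrices must share ids")
  n <- nrow(a)
  if (n < 3) stop("need at least 3 samples")
  av <- .upper_vec(a); bv <- .upper_vec(b)
  if (var(av) == 0 || var(bv) == 0) stop("constant matrix")
  r_obs <- cor(av, bv)
  if (exact) {
    perms <- .all_permutations(n)
    r_all <- apply(perms, 1, function(p) cor(.upper_vec(a[p, p]), bv))
    p <- mean(r_all >= r_obs - 1e-12)
    return(list(r = r_obs, p = p, permutations = nrow(perms)))
  }
  .with_seed(seed, {
    exceed <- 0L
    for (k in seq_len(permutations)) {
      perm <- sample.int(n)
      if (cor(.upper_vec(a[perm, perm]), bv) >= r_obs - 1e-12)
        exceed <- exceed + 1L
    }
  })
  list(r = r_obs, p = (1 + exceed) / (1 + permutations),
       permutations = permutations)
}
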