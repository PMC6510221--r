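#' Derive a per-stage seed from a master seed
#'
#' Fixed documented offsets keep every stochastic stage independently
#' reproducible from one master seed.
#'
#' @param seed master integer seed.
#' @param stage one of `"rarefy"`, `"nulldev"`, `"bnti"`, `"rc"`, `"mantel"`,
#'   `"regression"`.
#' @return integer seed.
#' @export
stageSeed <- function(seed, stage = c("rarefy", "nulldev", "bnti", "rc",
                                      "mantel", "regression")) {
  stage <- match.arg(stage)
  offset <- c(rarefy = 11L, nulldev = 13L, bnti = 17L, rc = 19L,
              mantel = 23L, regression = 29L)[[stage]]
  as.integer(seed) + offset
}

#' Run the full assembly-inference pipeline
#'
#' simulate (or accept) the data, rarefy, alpha diversity, within-site
#' Bray--Curtis null deviation, betaNTI, RC_bray, process classification and
#' per-site fractions, Mantel linkage of betaNTI to the environmental
#' covariate, pairwise regression, and per-site co-occurrence networks. The
#' null pool conventions follow the per-function documentation: null
#' deviation is computed within site (its site summary averages within-site
#' pairs); betaNTI and RC_bray use the full set of samples as the regional
#' pool so cross-site pairs are defined and the Mantel matrices cover all
#' samples.
#'
#' @param x a [scenarioConfig()] (the study is simulated) or an
#'   [AssemblyExperiment-class] with tree and `group` metadata.
#' @param reps null-model iterations for all three null statistics; the
#'   study convention is 999.
#' @param rarefy_depth even sampling depth; `NULL` skips rarefaction.
#' @param env_var metadata column to link assembly parameters to (default
#'   `"SOC"`).
#' @param seed master seed; defaults to the config's seed when `x` is a
#'   config.
#' @param rho_min,alpha,prevalence_min network screening parameters.
#' @return named list: `experiment`, `alpha`, `null_deviation` (per-site
#'   long table), `site_null_deviation`, `bnti`, `rc`, `pairs` (joined +
#'   labels), `fractions_by_site`, `fractions_overall`, `mantel`,
#'   `regression`, `networks` (one [CooccurrenceNetwork-class] per site).
#' @export
runAssemblyPipeline <- function(x, reps = 999, rarefy_depth = 4020,
                                env_var = "SOC", seed = NULL,
                                rho_min = 0.6, alpha = 0.05,
                                prevalence_min = 5) {
  if (inherits(x, "ScenarioConfig")) {
    if (is.null(seed)) seed <- x$seed
    ae <- simulateStudy(x)
  } else if (is(x, "AssemblyExperiment")) {
    if (is.null(seed)) seed <- 1L
    ae <- x
  } else stop("x must be a ScenarioConfig or an AssemblyExperiment")
  if (!is.null(rarefy_depth)) ae <- rarefy(ae, rarefy_depth, seed = stageSeed(seed, "rarefy"))
  counts <- otuCounts(ae)
  groups <- sampleGroups(ae)
  alpha_tab <- alphaDiversity(ae)

  # within-site null deviation (one pool per site)
  nd_list <- lapply(split(names(groups), groups), function(ids) {
    if (length(ids) < 2) return(NULL)
    nullDeviation(counts[, ids, drop = FALSE], reps = reps,
                  seed = stageSeed(seed, "nulldev"))
  })
  nd <- do.call(rbind, nd_list[!vapply(nd_list, is.null, logical(1))])
  rownames(nd) <- NULL
  site_nd <- siteNullDeviationSummary(nd, groups)

  bnti_tab <- betaNTI(counts, phyloTree(ae), reps = reps,
                      seed = stageSeed(seed, "bnti"))
  rc_tab <- raupCrickBray(counts, reps = reps, seed = stageSeed(seed, "rc"))
  pairs <- joinPairStatistics(bnti_tab, rc_tab)
  frac_site <- processFractions(pairs, groups)
  frac_all <- processFractions(pairs, NULL)

  meta <- as.data.frame(SummarizedExperiment::colData(ae))
  mantel_res <- regress_res <- NULL
  if (env_var %in% colnames(meta)) {
    bnti_mat <- pairwiseToMatrix(pairs, "bnti", ids = colnames(counts))
    env_mat <- envDifferenceMatrix(meta, env_var)
    shared <- intersect(rownames(env_mat), colnames(counts))
    # drop samples until every remaining pair has a defined betaNTI
    bm_na <- bnti_mat[shared, shared]
    while (anyNA(bm_na) && nrow(bm_na) > 3) {
      worst <- which.max(rowSums(is.na(bm_na)))
      bm_na <- bm_na[-worst, -worst, drop = FALSE]
    }
    shared <- rownames(bm_na)
    if (length(shared) >= 3 && !anyNA(bm_na)) {
      bm <- bnti_mat[shared, shared]; em <- env_mat[shared, shared]
      mantel_res <- mantelTest(bm, em, permutations = 999,
                               seed = stageSeed(seed, "mantel"))
      regress_res <- pairwiseRegression(em, bm, permutations = 999,
                                        seed = stageSeed(seed, "regression"))
    }
  }

  networks <- lapply(split(names(groups), groups), function(ids)
    cooccurrenceNetwork(counts[, ids, drop = FALSE], rho_min = rho_min,
                        alpha = alpha, prevalence_min = prevalence_min))

  list(experiment = ae, alpha = alpha_tab, null_deviation = nd,
       site_null_deviation = site_nd, bnti = bnti_tab, rc = rc_tab,
       pairs = pairs, fractions_by_site = frac_site,
       fractions_overall = frac_all, mantel = mantel_res,
       regression = regress_res, networks = networks)
}
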