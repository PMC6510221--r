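#' Scenario configuration for the community simulator
#'
#' Bundles and validates the parameters of [simulateStudy()]. The defaults
#' describe the demo-scale study the package analyses end-to-end: a regional
#' pool of 600 OTUs organised as 200 lineages of 3 closely related OTUs
#' (mirroring how 97%-similarity OTUs cluster within genera), 3 sites x 8
#' samples, 5,000 reads per sample (so the conventional rarefaction depth of
#' 4,020 applies verbatim), Brownian niche-optimum evolution at rate 1 on a
#' unit-height backbone, and a Gaussian environmental filter of breadth 0.1 on the environmental axis.
#'
#' Drift enters at two levels, mapped to the regimes the way ecological
#' theory predicts drift intensity: under selection an establishment lottery
#' redistributes each lineage's abundance among its member OTUs (`lottery`);
#' under dispersal limitation community-wide demographic drift is strong
#' (`drift_dispersion`); under mass effects (neutral dispersal) communities
#' are well-mixed samples of the metacommunity and drift is negligible.
#'
#' @param n_taxa regional pool size (>= 10; must be a multiple of
#'   `cluster_size`).
#' @param n_samples_per_site,n_sites sampling design.
#' @param regime assembly regime: `"variable_selection"` (environment varies
#'   strongly within every site), `"homogeneous_selection"` (one environment
#'   everywhere), `"neutral_dispersal"` (selection off, shared pool, no
#'   drift) or `"dispersal_limited"` (selection off, independent subsampled
#'   pools, strong drift).
#' @param selection_sd niche breadth sigma of the Gaussian environmental
#'   filter, in units of the environmental axis.
#' @param trait_signal Brownian-motion rate of niche-optimum evolution
#'   (variance per unit branch length).
#' @param reads_per_sample sequencing depth of each sample.
#' @param env_gradient list of per-site `c(min, max)` environmental ranges;
#'   `NULL` gives every site the same strong gradient (half-width 1.2) with
#'   small per-site offsets so no two samples share an identical environment.
#' @param dispersal_fraction fraction of the pool reachable by a sample under
#'   `"dispersal_limited"`.
#' @param cluster_size OTUs per terminal lineage radiation of the simulated
#'   phylogeny (1 = plain pure-birth tree).
#' @param cluster_depth depth of the terminal radiations, as a fraction of
#'   total tree height.
#' @param lottery Dirichlet concentration of the within-lineage
#'   establishment lottery under the selection regimes (`Inf` disables it).
#' @param drift_dispersion Dirichlet-multinomial concentration of
#'   community-wide demographic drift under `"dispersal_limited"` (`Inf`
#'   reduces to a plain multinomial).
#' @param abund_meanlog,abund_sdlog log-normal regional-abundance parameters
#'   at the lineage level.
#' @param otu_sdlog additional log-normal spread among OTUs within a lineage.
#' @param soc_slope,soc_intercept,soc_noise_sd affine map from the latent
#'   environment to the SOC covariate (mg g^-1) plus Gaussian noise.
#' @param seed master seed; per-stage seeds are derived by fixed offsets.
#' @return validated list of class `ScenarioConfig`.
#' @export
scenarioConfig <- function(n_taxa = 600, n_samples_per_site = 8, n_sites = 3,
                           regime = c("variable_selection",
                                      "homogeneous_selection",
                                      "neutral_dispersal", "dispersal_limited"),
                           selection_sd = 0.10, trait_signal = 1,
                           reads_per_sample = 5000, env_gradient = NULL,
                           dispersal_fraction = 0.25,
                           cluster_size = 3, cluster_depth = 0.03,
                           lottery = 0.5, drift_dispersion = 15,
                           abund_meanlog = 0, abund_sdlog = 1,
                           otu_sdlog = 0.25,
                           soc_slope = 8, soc_intercept = 20, soc_noise_sd = 0.5,
                           seed = 1) {
  regime <- match.arg(regime)
  if (n_taxa < 10) stop("n_taxa must be >= 10")
  if (n_taxa %% cluster_size != 0)
    stop("n_taxa must be a multiple of cluster_size")
  if (selection_sd <= 0) stop("selection_sd must be positive")
  if (trait_signal <= 0) stop("trait_signal must be positive")
  if (reads_per_sample < 1) stop("reads_per_sample must be positive")
  if (dispersal_fraction <= 0 || dispersal_fraction > 1)
    stop("dispersal_fraction must be in (0, 1]")
  if (lottery <= 0 || drift_dispersion <= 0)
    stop("lottery and drift_dispersion must be positive")
  if (cluster_depth <= 0 || cluster_depth >= 1)
    stop("cluster_depth must be in (0, 1)")
  if (is.null(env_gradient)) {
    offsets <- if (n_sites > 1) seq(-0.05, 0.05, length.out = n_sites) else 0
    env_gradient <- lapply(offsets, function(o) c(o - 1.2, o + 1.2))
  }
  if (length(env_gradient) != n_sites) stop("need one env range per site")
  structure(list(n_taxa = n_taxa, n_samples_per_site = n_samples_per_site,
                 n_sites = n_sites, regime = regime,
                 selection_sd = selection_sd, trait_signal = trait_signal,
                 reads_per_sample = reads_per_sample,
                 env_gradient = env_gradient,
                 dispersal_fraction = dispersal_fraction,
                 cluster_size = cluster_size, cluster_depth = cluster_depth,
                 lottery = lottery, drift_dispersion = drift_dispersion,
                 abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
                 otu_sdlog = otu_sdlog,
                 soc_slope = soc_slope, soc_intercept = soc_intercept,
                 soc_noise_sd = soc_noise_sd, seed = seed),
            class = "ScenarioConfig")
}

#' Simulate a phylogeny scaled to unit height
#'
#' With `cluster_size = 1` (the default) a pure-birth (Yule) tree with
#' exponential branching times via [ape::rphylo()] (birth 1, death 0),
#' rescaled so every root-to-tip depth is 1, tips `OTU_1 ... OTU_n`. With
#' `cluster_size > 1` the pure-birth tree forms a backbone of
#' `n_taxa / cluster_size` lineages, and each backbone tip carries a shallow
#' terminal radiation of `cluster_size` OTUs at depth `cluster_depth`,
#' emulating the clusters of near-identical OTUs that fine-scale clustering
#' of 16S sequences produces; tips are then `OTU_<lineage>_<member>`. Both
#' forms are ultrametric with unit height.
#'
#' @param n_taxa number of tips (>= 2; a multiple of `cluster_size`).
#' @param seed optional integer seed.
#' @param cluster_size tips per terminal radiation (1 = plain Yule).
#' @param cluster_depth radiation depth as a fraction of tree height.
#' @return ultrametric rooted `phylo`.
#' @export
simulateTree <- function(n_taxa, seed = NULL, cluster_size = 1,
                         cluster_depth = 0.05) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  if (n_taxa %% cluster_size != 0)
    stop("n_taxa must be a multiple of cluster_size")
  n_back <- n_taxa / cluster_size
  if (cluster_size > 1 && n_back < 2)
    stop("need at least 2 backbone lineages")
  tr <- .with_seed(seed, ape::rphylo(n_back, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  if (cluster_size == 1) {
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- paste0("OTU_", seq_len(n_taxa))
    return(tr)
  }
  tr$edge.length <- tr$edge.length / depth * (1 - cluster_depth)
  tr$tip.label <- paste0("L", seq_len(n_back), "q")   # sentinel suffix
  nwk <- ape::write.tree(tr)
  for (k in seq_len(n_back)) {
    rad <- paste0("(", paste0("OTU_", k, "_", seq_len(cluster_size), ":",
                              cluster_depth, collapse = ","), ")")
    nwk <- sub(paste0("L", k, "q:"), paste0(rad, ":"), nwk, fixed = TRUE)
  }
  ape::read.tree(text = nwk)
}

# lineage index of each tip of a simulated tree (1 for unclustered trees)
.tip_lineage <- function(labels) {
  out <- suppressWarnings(as.integer(sub("^OTU_([0-9]+)_[0-9]+$", "\\1", labels)))
  if (anyNA(out)) out <- seq_along(labels)   # unclustered: every tip its own
  out
}

#' Evolve niche optima along a tree by Brownian motion
#'
#' Root value 0; a tip's optimum is normal with variance
#' `rate x root-to-tip length`. Phylogenetically conserved optima are what
#' make the tip-shuffle null of [betaNTI()] informative.
#'
#' @param tree a `phylo` with branch lengths.
#' @param rate Brownian rate (variance per unit branch length), > 0.
#' @param seed optional integer seed.
#' @return named numeric vector of per-tip optima.
#' @export
evolveOptima <- function(tree, rate, seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  .with_seed(seed,
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate), root.value = 0))
}

#' Simulate one community under Gaussian environmental filtering
#'
#' Expected taxon weights are
#' \eqn{w_i \propto m_i \exp(-(o_i - env)^2 / (2\sigma^2))}, where \eqn{m_i}
#' are regional abundances and \eqn{o_i} niche optima. `sigma = Inf` switches
#' selection off (weights proportional to \eqn{m_i}); `pool_mask` restricts
#' the reachable pool (dispersal limitation). Two optional drift stages act
#' before the reads are drawn multinomially: a within-lineage establishment
#' lottery (each lineage's expected share is redistributed among its member
#' OTUs by a Dirichlet draw with concentration `lottery`) and community-wide
#' Dirichlet-multinomial drift with concentration `dispersion`.
#'
#' @param optima named per-taxon optima from [evolveOptima()].
#' @param env environmental value at the sample.
#' @param abundances regional abundances \eqn{m_i} (same order as `optima`).
#' @param sigma niche breadth; `Inf` for neutral.
#' @param reads number of reads to draw.
#' @param pool_mask logical vector marking reachable taxa, or `NULL` for all.
#' @param dispersion community-wide Dirichlet-multinomial concentration;
#'   `Inf` for none.
#' @param lineage integer vector assigning taxa to lineages (required for a
#'   finite `lottery`).
#' @param lottery within-lineage Dirichlet concentration; `Inf` for none.
#' @param seed optional integer seed.
#' @return named count vector over all taxa.
#' @export
simulateCommunity <- function(optima, env, abundances, sigma, reads,
                              pool_mask = NULL, dispersion = Inf,
                              lineage = NULL, lottery = Inf, seed = NULL) {
  if (!is.infinite(sigma) && sigma <= 0) stop("sigma must be positive or Inf")
  if (dispersion <= 0 || lottery <= 0)
    stop("dispersion and lottery must be positive")
  if (is.finite(lottery) && is.null(lineage))
    stop("a finite lottery requires lineage assignments")
  w <- if (is.infinite(sigma)) abundances else
    abundances * exp(-(optima - env)^2 / (2 * sigma^2))
  if (!is.null(pool_mask)) w <- w * pool_mask
  if (sum(w) <= 0) stop("no taxon has positive weight")
  x <- .with_seed(seed, {
    p <- w / sum(w)
    if (is.finite(lottery)) {
      pl <- tapply(p, lineage, sum)
      share <- ifelse(pl[lineage] > 0, p / pl[lineage], 0)
      g <- stats::rgamma(length(p), shape = lottery * share, rate = 1)
      gl <- tapply(g, lineage, sum)
      q <- ifelse(gl[lineage] > 0, pl[lineage] * g / gl[lineage], 0)
      if (sum(q) > 0) p <- as.numeric(q)
    }
    if (is.finite(dispersion)) {
      g <- stats::rgamma(length(p), shape = dispersion * p / sum(p), rate = 1)
      if (sum(g) > 0) p <- g
    }
    as.numeric(rmultinom(1, reads, prob = p))
  })
  names(x) <- names(optima)
  x
}

#' Simulate a multi-site assembly study
#'
#' Generates the lineage-structured tree, phylogenetically conserved niche
#' optima, log-normal regional abundances, per-site environments according
#' to the regime, the resulting OTU table, and sample metadata carrying the
#' site label, the latent environment, an SOC covariate (affine in the
#' environment plus noise) and an uninformative pH column.
#'
#' Regime mapping: under `variable_selection` the environment is evenly
#' spaced across each site's gradient and the within-lineage lottery is
#' active; under `homogeneous_selection` the environment is the overall
#' gradient midpoint everywhere, lottery active; `neutral_dispersal` draws
#' plain multinomial samples of the shared pool (mass effects, no drift);
#' `dispersal_limited` gives every sample an independent random subset of
#' the pool plus strong community-wide drift.
#'
#' @param config a [scenarioConfig()].
#' @return an [AssemblyExperiment-class] with tree and metadata attached.
#' @export
simulateStudy <- function(config) {
  stopifnot(inherits(config, "ScenarioConfig"))
  n_samples <- config$n_sites * config$n_samples_per_site
  tree <- simulateTree(config$n_taxa, seed = config$seed + 1L,
                       cluster_size = config$cluster_size,
                       cluster_depth = config$cluster_depth)
  lineage <- .tip_lineage(tree$tip.label)
  optima <- evolveOptima(tree, config$trait_signal, seed = config$seed + 2L)
  n_lin <- length(unique(lineage))
  abund <- .with_seed(config$seed + 3L, {
    m_lin <- rlnorm(n_lin, config$abund_meanlog, config$abund_sdlog)
    m_lin[lineage] * rlnorm(config$n_taxa, 0, config$otu_sdlog)
  })
  names(abund) <- tree$tip.label
  selective <- config$regime %in% c("variable_selection", "homogeneous_selection")
  mid <- mean(range(unlist(config$env_gradient)))
  env <- unlist(lapply(seq_len(config$n_sites), function(s) {
    rng <- config$env_gradient[[s]]
    if (config$regime == "variable_selection")
      seq(rng[1], rng[2], length.out = config$n_samples_per_site)
    else rep(mid, config$n_samples_per_site)
  }))
  sigma <- if (selective) config$selection_sd else Inf
  lottery <- if (selective) config$lottery else Inf
  dispersion <- if (config$regime == "dispersal_limited")
    config$drift_dispersion else Inf
  counts <- matrix(0, config$n_taxa, n_samples,
                   dimnames = list(tree$tip.label,
                                   sprintf("S%02d", seq_len(n_samples))))
  for (s in seq_len(n_samples)) {
    mask <- NULL
    if (config$regime == "dispersal_limited") {
      mask <- logical(config$n_taxa)
      pick <- .with_seed(config$seed + 100L + s,
        sample.int(config$n_taxa,
                   max(2, round(config$dispersal_fraction * config$n_taxa))))
      mask[pick] <- TRUE
    }
    counts[, s] <- simulateCommunity(optima, env[s], abund, sigma,
                                     config$reads_per_sample, pool_mask = mask,
                                     dispersion = dispersion,
                                     lineage = lineage, lottery = lottery,
                                     seed = config$seed + 1000L + s)
  }
  soc <- .with_seed(config$seed + 4L,
    config$soc_intercept + config$soc_slope * env +
      rnorm(n_samples, sd = config$soc_noise_sd))
  ph <- .with_seed(config$seed + 5L, rnorm(n_samples, mean = 6.5, sd = 0.3))
  meta <- data.frame(
    group = rep(paste0("site", seq_len(config$n_sites)),
                each = config$n_samples_per_site),
    env = env, SOC = soc, pH = ph,
    row.names = colnames(counts))
  AssemblyExperiment(counts, metadata = meta, tree = tree)
}
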