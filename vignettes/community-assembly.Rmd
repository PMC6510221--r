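---
title: "Quantifying deterministic and stochastic community assembly from OTU tables"
author: "assemblyscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deterministic and stochastic community assembly from OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Microbial communities are structured by a continuum of deterministic
processes (environmental selection, either *variable* across habitats or
*homogeneous* within them) and stochastic processes (drift plus dispersal
that is either *limiting* or *homogenizing*). `assemblyscope` implements the
null-model machinery used to locate a set of samples on that continuum from
three inputs: an OTU count table, a rooted phylogeny of the OTUs, and sample
metadata with site labels and environmental covariates.

```{r, eval = FALSE}
library(assemblyscope)
cfg <- scenarioConfig(regime = "variable_selection", seed = 1)
res <- runAssemblyPipeline(cfg, reps = 199)
res$fractions_by_site
```

## The statistics and their null models

**Beta-diversity null deviation.** For each sample pair the observed
Bray–Curtis dissimilarity is compared with its expectation under a
randomization that reassembles every sample while preserving its richness
and total reads: taxa are drawn without replacement with probability
proportional to their occurrence frequency across the pool samples, each
receives one individual, and the remaining reads are placed multinomially in
proportion to mean relative abundance (`assembleNullCommunity()`). Values
near zero mean the pair looks like a chance draw from the regional pool;
large deviations of either sign indicate deterministic structuring. Both the
plain deviation (observed − null mean) and the relative deviation
(divided by the null mean) are reported, because "relative difference" admits
both readings; the per-site summary defaults to the relative form. The
regional pool is whatever set of samples is passed to the call — per-site
analyses pass one site at a time.

**βMNTD and βNTI.** Phylogenetic turnover between two communities is the
abundance-weighted mean distance from each taxon to its nearest taxon in the
other community,
\[
\beta\mathrm{MNTD} = \tfrac12\Bigl[\sum_i f_i \min_j d_{ij} +
\sum_j g_j \min_i d_{ji}\Bigr],
\]
with a taxon present in both communities contributing distance zero (so
identical communities score 0). The null shuffles taxon identities across
the tips of the phylogeny — equivalently permutes rows and columns of the
cophenetic matrix jointly — holding compositions fixed; one shuffle per
replicate is shared by all pairs. βNTI is the z-score of the observed value
against that null. |βNTI| > 2 indicates selection: communities more
phylogenetically divergent than the null (> +2, variable selection) or more
similar (< −2, homogeneous selection). Pairs whose null standard deviation
is numerically zero (shuffle-invariant geometry, e.g. an equal-branch star
tree) are flagged `NA` rather than scored.

**RC~bray~.** The abundance-weighted Raup–Crick metric locates the observed
Bray–Curtis value within the distribution over null tables built by the same
richness- and abundance-preserving assembly, with ties given half weight,
rescaled to \([-1, +1]\). With |βNTI| < 2, RC~bray~ > +0.95 is read as
dispersal limitation and RC~bray~ < −0.95 as homogenizing dispersal; the
same null-community generator serves both this metric and the null deviation
so the two models stay consistent.

**Classification.** `classifyPair()` applies the strict thresholds
(βNTI > +2; βNTI < −2; |βNTI| < 2 with RC beyond ±0.95) and assigns
everything else — including values exactly on a boundary — to the residual
class `undominated`, so the five labels always partition the plane.
Fractions are tallied per site over defined pairs, with undefined βNTI pairs
counted separately.

**Environment linkage.** βNTI matrices are related to pairwise
environmental-difference matrices (|SOC~i~ − SOC~j~| and analogues) by a
permutation Mantel test (upper-triangle Pearson r; one-sided p with the +1
correction; an exhaustive mode enumerates all label permutations for up to 7
samples) and by ordinary least squares on the vectorized upper triangles.
Because pairwise observations share samples, the regression's headline
p-value is Mantel-style permutational; the parametric p is also returned,
labelled naive. The regression is on pairwise *differences* of the
environmental variable — the only form commensurate with a pairwise
response.

**Co-occurrence networks.** Spearman correlations (midranks) are computed on
per-sample relative abundances for taxa passing a prevalence filter
(default: present in ≥ 5 samples; the filter avoids rank-degenerate vectors
and is configurable down to 1 = none). P-values use the large-sample t
approximation on the rank correlation — the p that `psych::corr.test`
reports — and are Benjamini–Hochberg adjusted over all tested pairs. Kept
edges satisfy |ρ| > 0.6 *and* adjusted p < 0.05; the magnitude reading of
the threshold is deliberate, since negative (mutual-exclusion) edges are
part of the analysis. Modules come from greedy modularity maximization
(`igraph::cluster_fast_greedy`), topology metrics follow the usual
conventions (mean local clustering with degree-<2 nodes contributing 0; mean
shortest path over connected pairs; Freeman betweenness centralization), and
node roles use the within-module degree z-score and participation
coefficient with the standard thresholds Z = 2.5, P = 0.62. Correlations on
relative abundances carry the usual compositional caveat; no log-ratio
transform is applied by default.

## The synthetic study generator

Because the motivating soil dataset is not publicly deposited, the package
ships a generator whose regimes make every inference stage testable against
a known truth.

*Phylogeny.* `simulateTree()` produces a pure-birth tree scaled to unit
height. For the study simulator the tree is two-level: a pure-birth backbone
of lineages, each carrying a shallow terminal radiation (default 3 OTUs at
depth 0.03). This mirrors a real property of 97%-similarity OTU tables —
clusters of near-identical sequences within genera — that the
nearest-taxon metrics lean on: without terminal redundancy, turnover happens
between distant tips and βNTI loses its contrast against the tip-shuffle
null. On a unit-height pure-birth tree alone, Brownian optima of non-sister
tips are nearly independent, so filtering selects a phylogenetically
unstructured set of taxa.

*Niches and abundances.* Optima evolve by Brownian motion (rate 1) from a
root value of 0; regional abundances are log-normal at the lineage level
(meanlog 0, sdlog 1) with a further sdlog 0.25 spread among the OTUs of a
lineage. A sample at environment $e$ weights taxon $i$ by
$m_i \exp(-(o_i - e)^2 / 2\sigma^2)$ with niche breadth $\sigma = 0.1$.

*Regimes and drift.* Drift intensity follows dispersal theory: under the two
selection regimes an establishment lottery (Dirichlet concentration 0.5)
redistributes each lineage's expected share among its member
OTUs, creating the turnover-among-close-relatives signature that selection
plus local neutrality produces; under dispersal limitation every sample sees
an independent random 25% of the pool and strong community-wide
Dirichlet-multinomial drift (concentration 15); under mass-effects
neutrality samples are plain multinomial draws of the shared pool. Under
variable selection every site spans the same strong gradient (±1.2, with
±0.05 per-site offsets so no two samples share an environment); homogeneous
selection fixes the environment at the gradient midpoint. SOC is an affine
function of the latent environment plus Gaussian noise (sd 0.5), so
environment-linked turnover is recoverable by the Mantel and regression
stages; pH is pure noise and serves as a negative control.

*Scale.* The default scenario is 600 OTUs (200 lineages × 3), 3 sites × 8
samples and 5,000 reads per sample, so the conventional rarefaction depth of
4,020 applies verbatim. At 199 null replicates the full pipeline runs in
roughly half a minute to a minute per regime on one CPU; tests and the
acceptance script use that scale.

*What passing tests do and do not show.* The generator encodes Gaussian
niches, Brownian trait evolution, log-normal abundances and
Dirichlet-multinomial drift. Real soil data add sequencing error, chimeras,
compositional artefacts, taxonomic mis-clustering and spatial structure that
the generator deliberately omits, so regime recovery here demonstrates the
*inference machinery* is correct and well-calibrated under its own model
assumptions — not that the thresholds are unbiased for any real dataset.
The neutral scenario in particular saturates richness (most of the pool
present in every sample), which makes βNTI z-scores noisy there; that is a
property of saturated tables generally, and the undefined-flagging rules
make it visible rather than hiding it.

## Numerical and design choices

* **Rarefaction** is subsampling without replacement (multivariate
  hypergeometric); samples under depth are dropped with a warning, never
  padded. Coverage and α-diversity are computed on whatever table they are
  given — whether before or after rarefaction is the caller's choice, since
  the convention is ambiguous in the literature this package serves.
* **Shannon** uses natural logs (a base argument exists); **Simpson**
  defaults to the Gini–Simpson form 1 − Σp², with the dominance form
  selectable. **ACE** uses the rare/abundant threshold 10 and falls back to
  Chao1 with a warning when every rare taxon is a singleton (sample coverage
  0). **Faith's PD** is root-inclusive, matching common QIIME behaviour;
  root-exclusive tools will read lower.
* **Seeds.** Every randomized function takes an explicit seed;
  `runAssemblyPipeline()` derives per-stage seeds from one master seed by
  fixed offsets (`stageSeed()`), so each stage is independently
  reproducible and the whole pipeline is bit-identical under one seed.
* **Ties and boundaries.** RC~bray~ ties get half weight (equality judged at
  1e−10); classification boundaries fall to `undominated`; Mantel and
  regression permutation counts default to 999 with the +1 correction.
* **Degenerate inputs.** Readers reject duplicated ids, negative and
  non-integer counts rather than coercing; trees without branch lengths are
  zero-filled with a warning (strict mode rejects); βNTI with a zero null sd
  is flagged, and modules of size 1 receive a within-module degree z of 0.
* **Unweighted βMNTD** averages the two community means (the form the
  weighted definition reduces to); implementations that pool taxa across
  both communities differ when richness is unbalanced.

## Known limitations

The null models treat the sample set handed to them as the regional pool;
results therefore change with pooling choices (per-site versus global), and
both conventions are exposed. Spearman-screen p-values are asymptotic and
anti-conservative for very few samples — per-site networks from eight
samples routinely come back empty at FDR 0.05, which is the honest outcome,
not a failure. The compositional nature of relative abundances is not
corrected. Process fractions inherit the discreteness of their thresholds:
a pair at βNTI = 1.99 and one at 2.01 are ecologically indistinguishable but
counted in different classes.
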