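# assemblyscope

Null-model inference of microbial community assembly processes from OTU
count tables, a rooted phylogeny and sample metadata.

Soil (and other) microbial communities are shaped by a continuum between
deterministic processes — environmental selection that varies across
habitats or acts uniformly within them — and stochastic processes — drift
combined with limited or massive dispersal. `assemblyscope` implements the
standard null-model toolkit for placing a set of samples on that continuum:

* **β-diversity null deviation** — observed Bray–Curtis dissimilarity minus
  its expectation under a randomization preserving each sample's richness
  and total abundance (reported in plain and relative form);
* **βMNTD / βNTI** — abundance-weighted between-community
  mean-nearest-taxon distance and its z-score against a tip-shuffle null,

  βNTI = (βMNTD_obs − mean βMNTD_null) / sd βMNTD_null,

  with βNTI > +2 read as variable selection and βNTI < −2 as homogeneous
  selection;
* **RC_bray** — the abundance-weighted Raup–Crick metric in [−1, +1];
  together with |βNTI| < 2, RC_bray > +0.95 indicates dispersal limitation
  and RC_bray < −0.95 homogenizing dispersal, with the remainder
  undominated;
* **environment linkage** — permutation Mantel tests and pairwise
  regressions of βNTI against environmental-difference matrices (SOC is the
  shipped headline variable);
* **co-occurrence networks** — Spearman screens at |ρ| > 0.6 with
  Benjamini–Hochberg FDR < 0.05, greedy-modularity modules, topology
  summaries and Zi–Pi node roles (peripherals, module hubs, connectors,
  network hubs);
* **α-diversity** — Sobs, Chao1, ACE, Shannon, Simpson, Faith's PD and
  Good's coverage, plus rarefaction by subsampling without replacement;
* a **synthetic study generator** producing phylogenies, trait-structured
  regional pools, communities under four known assembly regimes and
  correlated environmental covariates, so every inference stage is testable
  without external data.

Data live in an `AssemblyExperiment`, a `SummarizedExperiment` subclass
carrying the taxa × samples count assay, the sample metadata and the
phylogeny; networks come back as `CooccurrenceNetwork` objects.

## Worked example

Simulate a three-site study under variable selection and run the whole
pipeline (rarefy → α-diversity → null deviation → βNTI → RC_bray →
classification → Mantel → networks):

```r
library(assemblyscope)

cfg <- scenarioConfig(regime = "variable_selection", seed = 1)
res <- runAssemblyPipeline(cfg, reps = 199)

res$fractions_by_site[, c("group", "variable_selection", "undominated", "n_pairs")]
#>   group variable_selection undominated n_pairs
#> 1 site1          0.6428571   0.1071429      28
#> 2 site2          0.6428571   0.1428571      28
#> 3 site3          0.6428571   0.1428571      28

res$mantel
#> $r
#> [1] 0.8369692
#> $p
#> [1] 0.001
```

Within every site, about 64% of sample pairs are classified as variable
selection (βNTI > +2 with the simulated environmental gradient driving
phylogenetic turnover), and the Mantel test ties the βNTI matrix to the
SOC difference matrix (r = 0.84, p = 0.001) — the qualitative signature a
gradient-structured soil dataset shows. Re-running with
`regime = "neutral_dispersal"` collapses the selection fractions and pushes
the null deviation toward zero.

Individual stages are exported on their own (`nullDeviation()`,
`betaNTI()`, `raupCrickBray()`, `classifyPair()`, `mantelTest()`,
`cooccurrenceNetwork()`, `alphaDiversity()`, …) and accept any
taxa × samples matrix plus `ape` tree, including ones read from disk with
`readAssemblyExperiment()`.

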