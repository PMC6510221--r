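#' Screen taxon pairs for co-occurrence edges
#'
#' Spearman rank correlation (midranks for ties) on per-sample relative
#' abundances for every retained taxon pair; p-values from the large-sample
#' t approximation on the rank correlation (the form psych::corr.test
#' reports), Benjamini--Hochberg adjusted over all tested pairs. Kept edges
#' satisfy |rho| > `rho_min` AND adjusted p < `alpha`; the sign of rho is
#' retained (negative edges are mutual-exclusion links). The |rho| reading of
#' the threshold is deliberate: printed thresholds of "r > 0.6" alongside
#' negative edges require it.
#'
#' @param counts taxa x samples matrix or an [AssemblyExperiment-class];
#'   at least 4 samples.
#' @param rho_min correlation magnitude threshold (default 0.6).
#' @param alpha FDR level on adjusted p-values (default 0.05).
#' @param prevalence_min retain taxa present in at least this many samples
#'   (default 5; 1 disables the filter).
#' @return data.frame of kept edges: `taxon_i`, `taxon_j`, `rho`, `p`,
#'   `p_adj`, `sign`. Attributes: `n_tested` (pairs entering BH),
#'   `n_constant` (pairs dropped for a constant vector, logged).
#' @export
spearmanEdgeScreen <- function(counts, rho_min = 0.6, alpha = 0.05,
                               prevalence_min = 5) {
  if (is(counts, "AssemblyExperiment")) counts <- otuCounts(counts)
  counts <- .check_counts(counts)
  if (ncol(counts) < 4) stop("need at least 4 samples")
  keep <- rowSums(counts > 0) >= prevalence_min
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) < 2)
    return(structure(data.frame(taxon_i = character(), taxon_j = character(),
                                rho = numeric(), p = numeric(),
                                p_adj = numeric(), sign = character()),
                     n_tested = 0L, n_constant = 0L))
  rel <- relativeAbundance(counts)
  n <- ncol(rel)
  rho <- suppressWarnings(cor(t(rel), method = "spearman"))
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  const <- is.na(r)
  if (any(const)) message(sum(const), " pair(s) with a constant vector excluded")
  idx <- idx[!const, , drop = FALSE]; r <- r[!const]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  p_adj <- stats::p.adjust(p, method = "BH")
  kept <- abs(r) > rho_min & p_adj < alpha
  out <- data.frame(
    taxon_i = rownames(rel)[idx[kept, 1]],
    taxon_j = rownames(rel)[idx[kept, 2]],
    rho = r[kept], p = p[kept], p_adj = p_adj[kept],
    sign = ifelse(r[kept] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  structure(out, n_tested = length(r), n_constant = sum(const))
}

#' Build a co-occurrence network from a screened edge list
#'
#' Undirected graph over the taxa incident to at least one kept edge
#' (isolated taxa never appear). Duplicate unordered pairs and self-loops are
#' rejected. The topology block and node roles are filled by
#' [modularityPartition()], [topologyMetrics()] and [nodeRoles()]; the
#' convenience wrapper [cooccurrenceNetwork()] runs the whole chain.
#'
#' @param edges data.frame with `taxon_i`, `taxon_j` and optionally `rho`.
#' @return a [CooccurrenceNetwork-class]; empty edge list gives an empty
#'   network with `NA` topology.
#' @export
buildNetwork <- function(edges) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (any(edges$taxon_i == edges$taxon_j)) stop("self-loop in edge list")
    key <- paste(pmin(edges$taxon_i, edges$taxon_j),
                 pmax(edges$taxon_i, edges$taxon_j))
    if (anyDuplicated(key)) stop("duplicate pair in edge list")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  topo <- list(n_vertices = igraph::vcount(g), n_edges = igraph::ecount(g),
               avg_degree = if (igraph::vcount(g) > 0)
                 2 * igraph::ecount(g) / igraph::vcount(g) else NA_real_,
               modularity = NA_real_, n_modules = NA_integer_,
               avg_clustering = NA_real_, avg_path_length = NA_real_,
               betweenness_centralization = NA_real_)
  nodes <- data.frame(taxon = igraph::V(g)$name,
                      degree = igraph::degree(g),
                      stringsAsFactors = FALSE, row.names = NULL)
  new("CooccurrenceNetwork", graph = g, nodes = nodes, edges = edges,
      topology = topo)
}

#' Greedy modularity partition
#'
#' Module detection by greedy modularity maximization
#' ([igraph::cluster_fast_greedy()]) on the unweighted graph;
#' \eqn{Q = \sum_m (e_m/E - (d_m/2E)^2)}.
#'
#' @param network a [CooccurrenceNetwork-class] with at least one edge.
#' @return list: `membership` (named integer vector), `modularity` (Q),
#'   `n_modules`.
#' @export
modularityPartition <- function(network) {
  g <- networkGraph(network)
  if (igraph::ecount(g) == 0) stop("edgeless network")
  cl <- igraph::cluster_fast_greedy(g)
  mem <- igraph::membership(cl)
  list(membership = setNames(as.integer(mem), igraph::V(g)$name),
       modularity = igraph::modularity(g, mem),
       n_modules = length(unique(mem)))
}

#' Topology summary of a network
#'
#' Average degree 2E/N; mean local clustering (degree < 2 nodes contribute
#' 0); average shortest-path length over connected pairs only; betweenness
#' normalized by (N-1)(N-2)/2; Freeman betweenness centralization.
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param partition output of [modularityPartition()], or `NULL` to leave
#'   modularity fields `NA`.
#' @return the topology list (see [CooccurrenceNetwork-class]).
#' @export
topologyMetrics <- function(network, partition = NULL) {
  g <- networkGraph(network)
  nv <- igraph::vcount(g); ne <- igraph::ecount(g)
  if (nv == 0)
    return(list(n_vertices = 0L, n_edges = 0L, avg_degree = NA_real_,
                modularity = NA_real_, n_modules = NA_integer_,
                avg_clustering = NA_real_, avg_path_length = NA_real_,
                betweenness_centralization = NA_real_))
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  loc[is.na(loc)] <- 0
  list(
    n_vertices = nv, n_edges = ne,
    avg_degree = 2 * ne / nv,
    modularity = if (!is.null(partition)) partition$modularity else NA_real_,
    n_modules = if (!is.null(partition)) partition$n_modules else NA_integer_,
    avg_clustering = mean(loc),
    avg_path_length = igraph::mean_distance(g, directed = FALSE),
    betweenness_centralization = igraph::centr_betw(g, directed = FALSE)$centralization
  )
}

#' Zi-Pi node roles
#'
#' Within-module degree z-score
#' \eqn{Z_i = (k_{i,m(i)} - \bar k_{m(i)}) / sd(k_{m(i)})} and participation
#' coefficient \eqn{P_i = 1 - \sum_m (k_{im}/k_i)^2}. Thresholds 2.5 / 0.62
#' split nodes into peripherals (specialists), module hubs and connectors
#' (generalists), and network hubs (super-generalists). Modules where the
#' within-degree sd is 0 (including size-1 modules) give Z = 0.
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param partition output of [modularityPartition()].
#' @param zi_threshold,pi_threshold role thresholds.
#' @return data.frame per node: `taxon`, `module`, `degree`, `zi`, `pi`,
#'   `role`.
#' @export
nodeRoles <- function(network, partition, zi_threshold = 2.5,
                      pi_threshold = 0.62) {
  g <- networkGraph(network)
  mem <- partition$membership[igraph::V(g)$name]
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(mem))
  # k_im: edges from node i into module m
  kim <- vapply(mods, function(m) rowSums(adj[, mem == m, drop = FALSE]),
                numeric(length(k)))
  kw <- kim[cbind(seq_along(k), match(mem, mods))]
  zi <- numeric(length(k))
  for (m in mods) {
    in_m <- mem == m
    s <- sd(kw[in_m])
    zi[in_m] <- if (sum(in_m) > 1 && s > 0) (kw[in_m] - mean(kw[in_m])) / s else 0
  }
  pi <- 1 - rowSums((kim / k)^2)
  role <- ifelse(zi > zi_threshold,
                 ifelse(pi > pi_threshold, "network_hub", "module_hub"),
                 ifelse(pi > pi_threshold, "connector", "peripheral"))
  data.frame(taxon = igraph::V(g)$name, module = as.integer(mem),
             degree = k, zi = zi, pi = pi,
             role = factor(role, levels = c("peripheral", "module_hub",
                                            "connector", "network_hub")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full co-occurrence network pipeline
#'
#' Screen, build, partition, summarize and assign roles in one call.
#'
#' @inheritParams spearmanEdgeScreen
#' @inheritParams nodeRoles
#' @return a [CooccurrenceNetwork-class] with topology and node table filled.
#' @export
cooccurrenceNetwork <- function(counts, rho_min = 0.6, alpha = 0.05,
                                prevalence_min = 5, zi_threshold = 2.5,
                                pi_threshold = 0.62) {
  edges <- spearmanEdgeScreen(counts, rho_min, alpha, prevalence_min)
  net <- buildNetwork(edges)
  if (nrow(edges) == 0) return(net)
  part <- modularityPartition(net)
  net@topology <- topologyMetrics(net, part)
  roles <- nodeRoles(net, part, zi_threshold, pi_threshold)
  bet <- igraph::betweenness(networkGraph(net), normalized = TRUE)
  roles$betweenness <- bet[roles$taxon]
  net@nodes <- roles
  net
}

#' Write a network to GraphML and TSV tables
#'
#' @param network a [CooccurrenceNetwork-class].
#' @param graphml,edges,nodes output paths (any may be `NULL` to skip).
#' @export
writeNetwork <- function(network, graphml = NULL, edges = NULL, nodes = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(networkGraph(network), graphml, format = "graphml")
  if (!is.null(edges)) writeLongTable(networkEdges(network), edges)
  if (!is.null(nodes)) writeLongTable(networkNodes(network), nodes)
  invisible(network)
}
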