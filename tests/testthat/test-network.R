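test_that("edge screening keeps strong correlations of either sign", {
  # taxa 1-2 co-increase, taxa 3 anti-tracks them; taxon 4 is noise
  m <- rbind(t1 = c(1, 2, 3, 4, 5, 6, 7, 8),
             t2 = c(2, 4, 5, 8, 9, 12, 13, 16),
             t3 = c(16, 13, 12, 9, 8, 5, 4, 2),
             t4 = c(5, 5, 4, 6, 5, 4, 6, 5) * 10)
  colnames(m) <- paste0("s", 1:8)
  edges <- spearmanEdgeScreen(m, rho_min = 0.6, alpha = 0.05,
                              prevalence_min = 1)
  key <- paste(edges$taxon_i, edges$taxon_j)
  expect_true("t1 t2" %in% key)
  expect_true("t1 t3" %in% key)
  expect_equal(edges$sign[key == "t1 t3"], "negative")
  expect_true(all(abs(edges$rho) > 0.6))
  expect_true(all(edges$p_adj < 0.05))
  # BH adjustment equals the hand formula (step-up with monotonicity)
  expect_equal(attr(edges, "n_tested"), 6)
})

test_that("BH adjustment inside the screen matches the hand-computed vector", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  hand <- rev(cummin(rev(p * 4 / seq_along(p))))
  expect_equal(hand, rep(0.04, 4))
  expect_equal(stats::p.adjust(p, "BH"), hand)
})

test_that("screening is monotone in the correlation threshold", {
  m <- random_counts(15, 8, lambda = 6, seed = 12)
  lo <- spearmanEdgeScreen(m, rho_min = 0.4, alpha = 0.4, prevalence_min = 1)
  hi <- spearmanEdgeScreen(m, rho_min = 0.7, alpha = 0.4, prevalence_min = 1)
  key <- function(e) paste(e$taxon_i, e$taxon_j)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("constant taxa are excluded with a logged count", {
  # equal column totals keep t3's relative abundance exactly constant
  m <- rbind(t1 = c(1, 2, 3, 4), t2 = c(4, 3, 2, 1), t3 = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  expect_message(edges <- spearmanEdgeScreen(m, prevalence_min = 1),
                 "constant")
  expect_equal(attr(edges, "n_constant"), 2L)   # both pairs involving t3
})

test_that("network construction enforces simple-graph invariants", {
  tri <- data.frame(taxon_i = c("a", "b", "c"), taxon_j = c("b", "c", "a"),
                    rho = c(0.9, 0.8, 0.7))
  net <- buildNetwork(tri)
  tp <- networkTopology(net)
  expect_equal(tp$n_vertices, 3)
  expect_equal(tp$n_edges, 3)
  expect_equal(tp$avg_degree, 2)
  expect_error(buildNetwork(rbind(tri, tri[1, ])), "duplicate")
  loop <- data.frame(taxon_i = "a", taxon_j = "a", rho = 1)
  expect_error(buildNetwork(loop), "self-loop")
  empty <- buildNetwork(tri[0, ])
  expect_equal(networkTopology(empty)$n_vertices, 0)
})

test_that("greedy modularity matches hand-computed Q on toy graphs", {
  # two triangles joined by one bridge: Q = 5/14 for the 2-module split
  e <- data.frame(taxon_i = c("a", "b", "c", "d", "e", "f", "c"),
                  taxon_j = c("b", "c", "a", "e", "f", "d", "d"))
  net <- buildNetwork(e)
  part <- modularityPartition(net)
  expect_equal(part$n_modules, 2)
  expect_equal(part$modularity, 5 / 14, tolerance = 1e-12)
  # hand evaluation of Q for the returned partition
  g <- networkGraph(net)
  mem <- part$membership[igraph::V(g)$name]
  E <- igraph::ecount(g)
  ends <- igraph::as_edgelist(g)
  q_hand <- sum(vapply(unique(mem), function(m) {
    inside <- sum(mem[ends[, 1]] == m & mem[ends[, 2]] == m)
    dm <- sum(igraph::degree(g)[mem == m])
    inside / E - (dm / (2 * E))^2
  }, numeric(1)))
  expect_equal(part$modularity, q_hand, tolerance = 1e-12)
  # two disconnected triangles: Q = 0.5
  e2 <- e[-7, ]
  part2 <- modularityPartition(buildNetwork(e2))
  expect_equal(part2$modularity, 0.5, tolerance = 1e-12)
  expect_equal(part2$n_modules, 2)
  # a single clique has no sub-structure: the 1-module partition scores 0
  # and no partition can beat it
  k4 <- as.data.frame(t(combn(letters[1:4], 2)))
  names(k4) <- c("taxon_i", "taxon_j")
  net4 <- buildNetwork(k4)
  expect_equal(igraph::modularity(networkGraph(net4), rep(1, 4)), 0,
               tolerance = 1e-12)
  expect_lte(modularityPartition(net4)$modularity, 0)
})

test_that("topology metrics match hand values on canonical graphs", {
  tri <- buildNetwork(data.frame(taxon_i = c("a", "b", "c"),
                                 taxon_j = c("b", "c", "a")))
  tp <- topologyMetrics(tri)
  expect_equal(tp$avg_clustering, 1)
  expect_equal(tp$avg_path_length, 1)
  expect_equal(tp$betweenness_centralization, 0)
  path <- buildNetwork(data.frame(taxon_i = c("a", "b"), taxon_j = c("b", "c")))
  tp2 <- topologyMetrics(path)
  expect_equal(tp2$avg_clustering, 0)
  expect_equal(tp2$avg_path_length, 4 / 3)
  expect_equal(unname(igraph::betweenness(networkGraph(path),
                                          normalized = TRUE)["b"]), 1)
  star <- buildNetwork(data.frame(taxon_i = "hub", taxon_j = letters[1:4]))
  expect_equal(topologyMetrics(star)$betweenness_centralization, 1)
})

test_that("Zi-Pi roles follow the threshold taxonomy", {
  # star with 4 leaves, leaves split across two declared modules:
  # hub degree 4 split 2/2 -> pi = 0.5
  star <- buildNetwork(data.frame(taxon_i = "hub", taxon_j = letters[1:4]))
  part <- list(membership = c(hub = 1L, a = 1L, b = 1L, c = 2L, d = 2L),
               modularity = 0, n_modules = 2L)
  roles <- nodeRoles(star, part)
  expect_equal(roles$pi[roles$taxon == "hub"], 0.5)
  expect_equal(roles$pi[roles$taxon == "a"], 0)    # all edges into module 1
  # symmetric clique as one module: everyone peripheral with zi = 0, pi = 0
  k4 <- as.data.frame(t(combn(letters[1:4], 2)))
  names(k4) <- c("taxon_i", "taxon_j")
  net <- buildNetwork(k4)
  p4 <- list(membership = setNames(rep(1L, 4), letters[1:4]),
             modularity = 0, n_modules = 1L)
  r4 <- nodeRoles(net, p4)
  expect_true(all(r4$zi == 0))
  expect_true(all(r4$pi == 0))
  expect_true(all(r4$role == "peripheral"))
  # exhaustive role partition over a zi/pi grid
  grid <- expand.grid(zi = c(-1, 0, 2.5, 3), pi = c(0, 0.62, 0.8))
  lab <- with(grid, ifelse(zi > 2.5,
                           ifelse(pi > 0.62, "network_hub", "module_hub"),
                           ifelse(pi > 0.62, "connector", "peripheral")))
  expect_equal(sort(unique(lab)),
               sort(c("peripheral", "module_hub", "connector", "network_hub")))
})

test_that("the full network pipeline fills topology and writes text formats", {
  cfg <- scenarioConfig(n_taxa = 90, n_samples_per_site = 8, n_sites = 1,
                        regime = "variable_selection", seed = 5)
  ae <- simulateStudy(cfg)
  net <- cooccurrenceNetwork(otuCounts(ae), rho_min = 0.6, alpha = 0.05,
                             prevalence_min = 3)
  tp <- networkTopology(net)
  expect_equal(tp$avg_degree, 2 * tp$n_edges / tp$n_vertices)
  if (tp$n_edges > 0) {
    expect_true(all(networkNodes(net)$role %in%
                    c("peripheral", "module_hub", "connector", "network_hub")))
    gml <- withr::local_tempfile(fileext = ".graphml")
    ed <- withr::local_tempfile(fileext = ".tsv")
    writeNetwork(net, graphml = gml, edges = ed)
    expect_true(file.exists(gml) && file.size(gml) > 0)
    expect_gt(nrow(utils::read.delim(ed)), 0)
  }
})
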