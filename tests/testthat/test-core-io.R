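test_that("OTU table round-trips in both orientations", {
  m <- toy_counts()
  p1 <- write_tsv_tmp(data.frame(taxon = rownames(m), m, check.names = FALSE))
  expect_identical(readOtuTable(p1), m)
  tm <- t(m)
  p2 <- write_tsv_tmp(data.frame(sample = rownames(tm), tm, check.names = FALSE))
  expect_equal(readOtuTable(p2, orientation = "samples_rows"),
               readOtuTable(p1))
  # orientation flip is an involution
  expect_equal(t(t(m)), m)
})

test_that("malformed OTU tables are rejected, not coerced", {
  m <- toy_counts()
  dup <- data.frame(taxon = c("t1", "t1", "t3"), m, check.names = FALSE)
  expect_error(readOtuTable(write_tsv_tmp(dup)), "duplicated")
  neg <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  neg$s1[2] <- -1
  expect_error(readOtuTable(write_tsv_tmp(neg)), "negative")
  frac <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  frac$s2[1] <- 2.5
  expect_error(readOtuTable(write_tsv_tmp(frac)), "non-integer")
})

test_that("newick trees parse with hand-checked path distances", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", p)
  tr <- readTree(p)
  d <- copheneticMatrix(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  writeLines("(A:1,B:1);", p)
  expect_equal(copheneticMatrix(readTree(p))["A", "B"], 2)
  writeLines("this is not newick((", p)
  expect_error(suppressWarnings(readTree(p)))
  # branches without lengths: warned and zero-filled, or rejected in strict mode
  writeLines("(A,B);", p)
  expect_warning(tr0 <- readTree(p), "branch lengths")
  expect_true(all(tr0$edge.length == 0))
  expect_error(readTree(p, strict = TRUE), "branch lengths")
})

test_that("metadata reader enforces ids and groups, keeps NA cells", {
  df <- data.frame(sample_id = c("s1", "s2", "s3"), group = "siteA",
                   pH = c(6.5, 7, NA), SOC = c(12, 15, 13))
  meta <- readSampleMetadata(write_tsv_tmp(df))
  expect_equal(rownames(meta), c("s1", "s2", "s3"))
  expect_equal(colnames(meta), c("group", "pH", "SOC"))
  expect_true(is.na(meta["s3", "pH"]))
  expect_error(readSampleMetadata(write_tsv_tmp(df[, -2])), "group")
  dup <- df; dup$sample_id[2] <- "s1"
  expect_error(readSampleMetadata(write_tsv_tmp(dup)), "duplicated")
})

test_that("rarefaction conserves depth and never exceeds originals", {
  x <- matrix(c(10L, 5L, 5L), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
  expect_equal(rarefyCounts(x, depth = 20), x * 1)   # depth equals total
  r <- rarefyCounts(x, depth = 10, seed = 7)
  expect_equal(sum(r), 10)
  expect_true(all(r <= x))
  expect_identical(r, rarefyCounts(x, depth = 10, seed = 7))
  m <- cbind(x, s2 = c(2L, 1L, 0L))
  expect_warning(r2 <- rarefyCounts(m, depth = 10, seed = 1), "dropping")
  expect_equal(colnames(r2), "s1")
  expect_error(rarefyCounts(m, depth = 100), "below")
})

test_that("rarefied proportions are unbiased (multivariate hypergeometric)", {
  x <- matrix(c(40L, 30L, 30L), 3, 1, dimnames = list(paste0("t", 1:3), "s1"))
  draws <- vapply(seq_len(200), function(s)
    rarefyCounts(x, depth = 50, seed = s)[1, 1] / 50, numeric(1))
  # hypergeometric mean 0.4; se of the mean over 200 seeds
  se <- sqrt(0.4 * 0.6 * (100 - 50) / (100 - 1) / 50) / sqrt(200)
  expect_lt(abs(mean(draws) - 0.4), 3 * se)
})

test_that("result tables and distance matrices round-trip", {
  df <- data.frame(sample_i = "a", sample_j = "b", bnti = 2.5)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLongTable(df, p)
  expect_equal(utils::read.delim(p), df)
  expect_error(writeLongTable(df[0, ], p), "empty")
  m <- matrix(c(0, 1.5, 1.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  writeDistanceMatrix(m, p)
  expect_equal(readDistanceMatrix(p), m, tolerance = 1e-12)
})

test_that("AssemblyExperiment validates counts, ids and tree coverage", {
  m <- toy_counts()
  ae <- AssemblyExperiment(m)
  expect_s4_class(ae, "AssemblyExperiment")
  expect_equal(otuCounts(ae), m * 1)
  expect_error(AssemblyExperiment(m - 3))            # negatives
  tr <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  ae2 <- AssemblyExperiment(m, tree = tr)
  expect_equal(sort(phyloTree(ae2)$tip.label), rownames(m))
  bad <- ape::read.tree(text = "(t1:1,t2:1);")       # t3 missing
  expect_error(AssemblyExperiment(m, tree = bad), "absent from tree")
  meta <- data.frame(group = c("g1", "g2"), row.names = c("s1", "s2"))
  ae3 <- AssemblyExperiment(m, metadata = meta)
  expect_equal(sampleGroups(ae3), c(s1 = "g1", s2 = "g2"))
})

test_that("rarefy method subsets samples and keeps the tree", {
  m <- random_counts(8, 4, lambda = 30)
  tr <- ape::rtree(8, tip.label = rownames(m))
  ae <- AssemblyExperiment(m, tree = tr)
  depth <- min(colSums(m))
  r <- rarefy(ae, depth = depth, seed = 3)
  expect_true(all(colSums(otuCounts(r)) == depth))
  expect_false(is.null(phyloTree(r)))
})
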