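test_that("pair classification follows the printed thresholds", {
  expect_equal(as.character(classifyPair(2.5, 0.1)), "variable_selection")
  expect_equal(as.character(classifyPair(-3, 0)), "homogeneous_selection")
  expect_equal(as.character(classifyPair(0.5, 0.99)), "dispersal_limitation")
  expect_equal(as.character(classifyPair(1.2, -0.97)), "homogenizing_dispersal")
  expect_equal(as.character(classifyPair(0, 0)), "undominated")
  # boundary values are strict: exactly +/-2 and +/-0.95 stay undominated
  expect_equal(as.character(classifyPair(c(2, -2, 0, 0), c(0, 0, 0.95, -0.95))),
               rep("undominated", 4))
  expect_error(classifyPair(NA, 0))
  expect_error(classifyPair(0, 1.2), "outside")
})

test_that("classification partitions the plane exhaustively and exclusively", {
  grid <- expand.grid(bnti = seq(-4, 4, by = 0.25),
                      rc = seq(-1, 1, by = 0.05))
  lab <- classifyPair(grid$bnti, grid$rc)
  expect_false(anyNA(lab))
  expect_setequal(levels(lab), processLevels)
  # re-deriving each rule independently reproduces the labels
  ref <- with(grid, ifelse(bnti > 2, "variable_selection",
              ifelse(bnti < -2, "homogeneous_selection",
              ifelse(abs(bnti) < 2 & rc > 0.95, "dispersal_limitation",
              ifelse(abs(bnti) < 2 & rc < -0.95, "homogenizing_dispersal",
                     "undominated")))))
  expect_equal(as.character(lab), ref)
})

test_that("process fractions partition within-group pairs", {
  pairs <- data.frame(
    sample_i = c("a", "a", "b", "a"), sample_j = c("b", "c", "c", "d"),
    process = factor(c("variable_selection", "homogeneous_selection",
                       "dispersal_limitation", "variable_selection"),
                     levels = processLevels))
  f <- processFractions(pairs, NULL)
  expect_equal(f$variable_selection, 0.5)
  expect_equal(sum(f[, processLevels]), 1)
  groups <- c(a = "g1", b = "g1", c = "g1", d = "g2")
  fg <- processFractions(pairs, groups)   # a-d is a between-group pair
  expect_equal(fg$n_pairs, 3)
  expect_equal(unname(unlist(fg[, processLevels])), c(1, 1, 1, 0, 0) / 3)
  # undefined pairs count but never enter a fraction
  pairs$process[2] <- NA
  f2 <- processFractions(pairs, NULL)
  expect_equal(f2$n_undefined, 1)
  expect_equal(sum(f2[, processLevels]), 1)
})

test_that("environmental difference matrices are |v_i - v_j|", {
  meta <- data.frame(group = "g", SOC = c(1, 4, 2), pH = c(7, 7, 7),
                     row.names = c("a", "b", "c"))
  m <- envDifferenceMatrix(meta, "SOC")
  expect_equal(m["a", "b"], 3)
  expect_equal(m["b", "c"], 2)
  expect_equal(envDifferenceMatrix(meta, "pH"), matrix(0, 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c"))))
  meta$SOC[2] <- NA
  expect_equal(rownames(envDifferenceMatrix(meta, "SOC")), c("a", "c"))
  meta$SOC <- NA
  expect_error(envDifferenceMatrix(meta, "SOC"), "missing")
  expect_error(envDifferenceMatrix(meta, "TN"), "not found")
})

test_that("pairwise regression recovers exact linear structure", {
  set.seed(2)
  v <- c(a = 1, b = 3, c = 6, d = 10)
  x <- abs(outer(v, v, "-")); dimnames(x) <- list(names(v), names(v))
  y <- 2 * x
  fit <- pairwiseRegression(x, y, permutations = 99, seed = 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$r, 1)
  expect_equal(fit$r_squared, 1)
  expect_error(pairwiseRegression(x[1:2, 1:2], y[1:2, 1:2]), "at least 3")
  con <- x; con[] <- 0
  expect_error(pairwiseRegression(con, y), "zero variance")
})

test_that("permutation p is approximately uniform under independence", {
  set.seed(31)
  ps <- replicate(30, {
    v1 <- rnorm(7); v2 <- rnorm(7)
    x <- abs(outer(v1, v1, "-")); y <- abs(outer(v2, v2, "-"))
    ids <- paste0("s", 1:7)
    dimnames(x) <- dimnames(y) <- list(ids, ids)
    pairwiseRegression(x, y, permutations = 99)$p_permutation
  })
  expect_gt(mean(ps), 0.25)           # not systematically anticonservative
  expect_lt(mean(ps < 0.1), 0.4)
})

test_that("Mantel r hits its algebraic extremes and exact enumeration", {
  v <- c(a = 0, b = 2, c = 5, d = 9)
  a <- abs(outer(v, v, "-")); dimnames(a) <- list(names(v), names(v))
  expect_equal(mantelTest(a, a, permutations = 19, seed = 1)$r, 1)
  b <- max(a) + 1 - a; diag(b) <- 0; dimnames(b) <- dimnames(a)
  expect_equal(mantelTest(a, b, permutations = 19, seed = 1)$r, -1)
  # exact mode equals an independent enumeration over all 4! = 24 label orders
  set.seed(6)
  w <- rnorm(4); u <- rnorm(4)
  a2 <- abs(outer(w, w, "-")); b2 <- abs(outer(u, u, "-"))
  ids <- paste0("s", 1:4)
  dimnames(a2) <- dimnames(b2) <- list(ids, ids)
  ex <- mantelTest(a2, b2, exact = TRUE)
  perms <- rbind(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                 c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
                 c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
                 c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                 c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  rs <- apply(perms, 1, function(p)
    cor(a2[p, p][upper.tri(a2)], b2[upper.tri(b2)]))
  expect_equal(ex$p, mean(rs >= ex$r - 1e-12))
  expect_equal(ex$permutations, 24)
})

test_that("Mantel agrees with vegan and is affine-invariant", {
  set.seed(14)
  v1 <- rnorm(8); v2 <- v1 + rnorm(8, sd = 0.5)
  a <- abs(outer(v1, v1, "-")); b <- abs(outer(v2, v2, "-"))
  ids <- paste0("s", 1:8)
  dimnames(a) <- dimnames(b) <- list(ids, ids)
  mine <- mantelTest(a, b, permutations = 999, seed = 5)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  scaled <- mantelTest(2 * a, 5 * b, permutations = 99, seed = 5)
  expect_equal(scaled$r, mine$r)
  expect_error(mantelTest(a, 0 * b), "constant")
})
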