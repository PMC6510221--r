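# shared toy fixtures, built in code

# balanced 4-tip tree: d(A,B) = 2, d(A,C) = 4, d(C,D) = 2
toy_tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# 3-tip caterpillar: pd({A,B}) = 3, pd({C}) = 2, total length 5
toy_tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 1L, 4L), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  m
}

# small random community table with guaranteed positive column sums
random_counts <- function(n_taxa, n_samples, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda) *
                rbinom(n_taxa * n_samples, 1, 0.7),
              n_taxa, n_samples,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  empty <- colSums(m) == 0
  m[1, empty] <- 1L
  m
}

write_tsv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, ...)
  path
}
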