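test_that("correlation distances follow the chosen transform", {
  corr <- matrix(c(1, -1, -1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  d_signed <- correlation_distance(corr, mode = "one_minus_r")
  expect_equal(d_signed["a", "b"], 2)
  d_abs <- correlation_distance(corr, mode = "one_minus_abs_r")
  expect_equal(d_abs["a", "b"], 0)
  corr2 <- diag(2)
  dimnames(corr2) <- dimnames(corr)
  expect_equal(correlation_distance(corr2)["a", "b"], 1)
  expect_equal(unname(diag(correlation_distance(corr))), c(0, 0))
  expect_error(correlation_distance(matrix(c(1, 2, 0.5, 1), 2, 2)), "symmetric")
})

test_that("small merges behave as expected", {
  # identical pair merges first at height zero
  d3 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  tr <- hierarchical_cluster(d3)
  expect_equal(tr$height[1], 0)
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("g1", "g2"))
  # cutting at height 0 (k = 2) groups exactly the zero-distance pair
  memb <- cluster_membership(tr, 2)
  expect_equal(memb[["g1"]], memb[["g2"]])
  expect_false(memb[["g1"]] == memb[["g3"]])

  # two items: one merge at their distance
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- hierarchical_cluster(d2)
  expect_equal(tr2$height, 0.7)
})

test_that("merge sequence matches the brute-force agglomeration oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 4
    m <- matrix(runif(n * n), n, n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
    for (linkage in c("average", "single", "complete")) {
      tr <- hierarchical_cluster(d, linkage = linkage)
      oracle <- brute_agglomerate(d, linkage = linkage)
      expect_equal(tr$height, oracle$heights, tolerance = 1e-12)
      for (step in seq_len(n - 1)) {
        memb <- cluster_membership(tr, n - step)
        expect_identical(canonical_partition(memb), oracle$partitions[[step]])
      }
    }
  }
})

test_that("heights are non-decreasing and invariant to input gene order", {
  set.seed(5)
  n <- 7
  m <- matrix(runif(n * n), n, n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("g", 1:n), paste0("g", 1:n))
  tr <- hierarchical_cluster(d)
  expect_true(all(diff(tr$height) >= -1e-12))
  perm <- sample(n)
  tr_perm <- hierarchical_cluster(d[perm, perm])
  expect_equal(tr$height, tr_perm$height, tolerance = 1e-12)
  for (k in 2:(n - 1)) {
    expect_identical(canonical_partition(cluster_membership(tr, k)),
                     canonical_partition(cluster_membership(tr_perm, k)))
  }
})

test_that("membership cuts cover the trivial extremes and reject bad k", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  nt <- build_network(d, "HT")
  tr <- hierarchical_cluster(correlation_distance(nt$corr))
  expect_equal(length(unique(cluster_membership(tr, 13))), 13)
  expect_equal(length(unique(cluster_membership(tr, 1))), 1)
  expect_error(cluster_membership(tr, 0), "between")
  expect_error(cluster_membership(tr, 14), "between")
})

test_that("a tight B-cell block separates from the rest at k = 2", {
  blocks <- list(gene_block("b_cell", c("CD19", "CD20"), within_rho = 0.95),
                 gene_block("t_cell", c("CD3G", "CTLA4"), within_rho = 0.4),
                 gene_block("myeloid", c("CD11b", "TLR9"), within_rho = 0.4))
  cfg <- synthetic_config(group_sizes = c(HT = 300), blocks = blocks,
                          cross_rho = 0.05, age_mean = c(HT = 30),
                          age_sd = c(HT = 10), seed = 23)
  d <- generate_dataset(cfg)
  nt <- build_network(d, "HT", log_transform = TRUE)
  tr <- hierarchical_cluster(correlation_distance(nt$corr))
  memb <- cluster_membership(tr, 2)
  expect_equal(memb[["CD19"]], memb[["CD20"]])
})

test_that("newick export round-trips through ape", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  nt <- build_network(d, "HT")
  tr <- hierarchical_cluster(correlation_distance(nt$corr))
  nwk <- as_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, d$genes)
  f <- file.path(tempdir(), "tree.nwk")
  as_newick(tr, file = f)
  expect_true(file.exists(f))
  unlink(f)
})
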