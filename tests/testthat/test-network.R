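test_that("pearson_cor matches hand computations and rejects degenerate input", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_cor(c(1, 2), c(1, 2)), "at least 3")
})

test_that("edge classification respects inclusive thresholds and sign symmetry", {
  expect_equal(classify_edge(0.95), "strong")
  expect_equal(classify_edge(-0.85), "moderate")
  expect_equal(classify_edge(0.5), "none")
  # boundaries are inclusive
  expect_equal(classify_edge(0.9), "strong")
  expect_equal(classify_edge(0.8), "moderate")
  expect_equal(classify_edge(-0.9), "strong")
  # sign symmetry over a sweep of r values
  r <- seq(-1, 1, by = 0.05)
  expect_identical(classify_edge(r), classify_edge(-r))
  expect_error(classify_edge(0.5, strong_thr = 0.7, moderate_thr = 0.8),
               "thresholds")
})

test_that("robust z outlier flagging finds spiked samples and nothing else", {
  set.seed(11)
  vals <- matrix(10 + rnorm(70 * 3), 70, 3,
                 dimnames = list(NULL, c("gA", "gB", "gC")))
  d0 <- expression_dataset(vals, rep("HT", 70), age = rep(30, 70))
  expect_length(flag_outliers(d0)$flagged, 0)

  # spike one sample far beyond the robust threshold
  med <- median(vals[, "gB"])
  madv <- mad(vals[, "gB"])
  vals[37, "gB"] <- med + 100 * madv
  d1 <- expression_dataset(vals, rep("HT", 70), age = rep(30, 70))
  rep1 <- flag_outliers(d1)
  expect_identical(rep1$flagged, "S37")
  expect_equal(nrow(d1$values) - length(rep1$flagged), 69)
  d2 <- drop_samples(d1, rep1$flagged)
  expect_equal(nrow(d2$values), 69)

  # identical samples: zero MAD everywhere, genes skipped, nothing flagged
  dconst <- expression_dataset(matrix(1, 10, 2, dimnames = list(NULL, c("a", "b"))),
                               rep("HT", 10), age = rep(30, 10))
  expect_warning(repc <- flag_outliers(dconst), "zero MAD")
  expect_length(repc$flagged, 0)
})

test_that("build_network computes all pairs, skips small groups, orders pairs", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)

  at <- build_network(d, "AT")
  expect_true(at$skipped)
  expect_match(at$reason, "too small")

  ht <- build_network(d, "HT")
  expect_false(ht$skipped)
  expect_equal(nrow(ht$edges), 78)
  expect_true(all(ht$edges$gene_a < ht$edges$gene_b))
  expect_equal(unname(diag(ht$corr)), rep(1, 13))
  expect_true(isSymmetric(ht$corr))
  # classes consistent with |r| and thresholds
  expect_identical(ht$edges$class, classify_edge(ht$edges$r))
})

test_that("exact linear dependence yields a strong unit edge", {
  set.seed(4)
  cd20 <- exp(rnorm(30))
  vals <- cbind(CD19 = 2 * cd20, CD20 = cd20, OTHER = exp(rnorm(30)))
  d <- expression_dataset(vals, rep("HT", 30), age = rep(30, 30))
  nt <- build_network(d, "HT")
  e <- nt$edges[nt$edges$gene_a == "CD19" & nt$edges$gene_b == "CD20", ]
  expect_equal(e$r, 1.0)
  expect_equal(e$class, "strong")
})

test_that("correlation network is invariant to positive affine per-gene rescaling", {
  cfg <- synthetic_config(group_sizes = c(HT = 40), age_mean = c(HT = 30),
                          age_sd = c(HT = 10), seed = 13)
  d <- generate_dataset(cfg)
  sc <- runif(13, 0.5, 3)
  d2 <- expression_dataset(sweep(d$values, 2, sc, "*"), d$group, d$age,
                           d$sample_id)
  n1 <- build_network(d, "HT")
  n2 <- build_network(d2, "HT")
  expect_equal(n1$corr, n2$corr, tolerance = 1e-12)
  expect_identical(n1$edges$class, n2$edges$class)
})

test_that("planted strong T-block correlation is detected on the log scale", {
  blocks <- list(gene_block("t_cell", c("CD3G", "CTLA4"), within_rho = 0.95),
                 gene_block("b_cell", c("CD19", "CD20"), within_rho = 0.5))
  cfg <- synthetic_config(group_sizes = c(HT = 500), blocks = blocks,
                          cross_rho = 0.1, age_mean = c(HT = 30),
                          age_sd = c(HT = 10), seed = 17)
  d <- generate_dataset(cfg)
  nt <- build_network(d, "HT", log_transform = TRUE)
  e <- nt$edges[nt$edges$gene_a == "CD3G" & nt$edges$gene_b == "CTLA4", ]
  expect_equal(e$class, "strong")
})

test_that("network comparison reports gains, losses, and strengthening", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  ht <- build_network(d, "HT")
  lt <- build_network(d, "LT")

  same <- compare_networks(ht, ht)
  expect_equal(nrow(same$gained), 0)
  expect_equal(nrow(same$lost), 0)

  cmp <- compare_networks(ht, lt)
  # the tightened LT group strengthens the network overall
  expect_gt(cmp$mean_abs_r_b, cmp$mean_abs_r_a)

  # degrading exactly one strong edge produces exactly one lost edge
  lt2 <- lt
  strong_idx <- which(lt2$edges$class == "strong")[1]
  lt2$edges$class[strong_idx] <- "none"
  cmp2 <- compare_networks(lt, lt2)
  expect_equal(nrow(cmp2$lost), 1)
  expect_equal(nrow(cmp2$gained), 0)

  ht_small <- build_network(drop_samples(d, character(0)), "HT")
  ht_small$genes <- ht_small$genes[-1]
  expect_error(compare_networks(ht, ht_small), "gene sets differ")
})

test_that("network files are written in standard formats", {
  cfg <- synthetic_config(seed = 7)
  d <- generate_dataset(cfg)
  nt <- build_network(d, "LT")
  prefix <- file.path(tempdir(), "netout")
  files <- write_network(nt, prefix)
  expect_true(all(file.exists(files)))
  g <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 13)
  expect_equal(igraph::gsize(g), sum(nt$edges$class != "none"))
  unlink(files)
})
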