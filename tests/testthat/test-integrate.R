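test_that("promoter means average observed levels and enforce the CpG floor", {
  # 12 CpGs all at level 0.5 -> mean 0.5; a 9-CpG promoter is dropped
  sites <- data.frame(chrom = "c1", pos = c(seq(100L, 155L, by = 5L),
                                            seq(1000L, 1040L, by = 5L)),
                      strand = "+")
  n1 <- 12; n2 <- 9
  meth <- matrix(5L, n1 + n2, 3)
  total <- matrix(10L, n1 + n2, 3)
  m <- meth_count_matrix(sites, c("a", "b", "c"), meth, total)
  proms <- region_set("c1", c(90L, 990L), c(160L, 1045L), "promoter")
  proms$gene_id <- c("gBig", "gSmall")
  pm <- promoter_mean_methylation(m, proms, min_cpgs = 10)
  expect_equal(rownames(pm$meth), "gBig")
  expect_equal(unname(pm$meth["gBig", ]), c(0.5, 0.5, 0.5))
  expect_equal(pm$dropped, "gSmall")
  # a sample missing every promoter cell gets NA, not 0
  meth2 <- meth; total2 <- total
  total2[1:n1, 2] <- NA_integer_; meth2[1:n1, 2] <- NA_integer_
  m2 <- meth_count_matrix(sites, c("a", "b", "c"), meth2, total2)
  pm2 <- promoter_mean_methylation(m2, proms, min_cpgs = 10)
  expect_true(is.na(pm2$meth["gBig", "b"]))
  expect_false(anyNA(pm2$meth["gBig", c("a", "c")]))
})

test_that("Spearman correlation matches a rank-then-Pearson oracle", {
  set.seed(515)
  for (rep in 1:5) {
    x <- rnorm(20); y <- rnorm(20)
    r <- spearman_methylation_expression(x, y)
    oracle <- cor(rank(x), rank(y))  # average ranks, Pearson on ranks
    expect_equal(r$rho, oracle, tolerance = 1e-12)
  }
  # strictly monotone decreasing -> rho = -1
  x <- 1:10 / 10
  y <- exp(-3 * x)
  r <- spearman_methylation_expression(x, y)
  expect_equal(r$rho, -1)
  expect_equal(r$sign, "negative")
  expect_equal(r$p_value, 0)
  # constant vector -> flagged NA, not an error
  rc <- spearman_methylation_expression(rep(0.4, 8), rnorm(8))
  expect_true(is.na(rc$rho))
  expect_false(rc$significant)
  expect_error(spearman_methylation_expression(1:3, 1:3), "5 complete")
})

test_that("correlation is invariant to strictly monotone transforms", {
  set.seed(99)
  x <- runif(15); y <- rnorm(15)
  base <- spearman_methylation_expression(x, y)
  tx <- spearman_methylation_expression(qlogis(pmin(pmax(x, 1e-6),
                                                    1 - 1e-6)), y)
  ty <- spearman_methylation_expression(x, exp(y))
  expect_equal(base$rho, tx$rho, tolerance = 1e-12)
  expect_equal(base$rho, ty$rho, tolerance = 1e-12)
})

test_that("rank-sum group test matches exact enumeration", {
  # {1,2,3} vs {10,11,12}: most extreme of C(6,3) = 20 assignments
  r <- group_expression_test(c(1, 2, 3, 10, 11, 12),
                             rep(c("a", "b"), each = 3))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  # identical groups
  ri <- group_expression_test(c(5, 6, 7, 5, 6, 7),
                              rep(c("a", "b"), each = 3))
  expect_gt(ri$p_value, 0.99)
  # all tied values -> p = 1 by convention
  rt <- group_expression_test(rep(4, 6), rep(c("a", "b"), each = 3))
  expect_equal(rt$p_value, 1)
  expect_error(group_expression_test(c(1, 2, 3), c("a", "b", "b")),
               "at least 2")
})

test_that("coupled genes are recovered and null coupling stays near alpha", {
  sim <- study_sim()
  fmat <- apply_site_filter(sim$matrix)
  proms <- promoter_windows(sim$genes, genome = sim$genome)
  pm <- promoter_mean_methylation(fmat, proms)
  tab <- correlate_promoters_expression(pm, sim$expr)
  truth <- sim$expr_truth
  hit <- tab[tab$gene_id %in% truth$gene_id, ]
  # at the default noise most coupled genes reach significance and every
  # recovered sign matches the planted coupling sign
  expect_gte(mean(hit$significant), 2 / 3)
  sgn <- truth$sign[match(hit$gene_id, truth$gene_id)]
  agree <- (hit$rho > 0) == (sgn > 0)
  expect_true(all(agree[hit$significant]))
  # uncoupled genes stay mostly non-significant
  others <- tab[!(tab$gene_id %in% truth$gene_id), ]
  if (nrow(others) > 0) expect_lte(mean(others$significant), 0.2)
  # strong coupling at low noise recovers essentially all coupled genes
  strong <- sim$config
  strong$coupling_slope <- 6
  strong$expression_noise_sd <- 0.2
  ex2 <- simulate_expression(sim$genes, sim$truth$promoter_meth, strong)
  tab2 <- correlate_promoters_expression(pm, ex2$expr)
  hit2 <- tab2[tab2$gene_id %in% ex2$truth$gene_id, ]
  expect_gte(mean(hit2$significant), 0.9)
})

test_that("site-gene assignment prefers promoter owner over host gene", {
  gA <- gene_model("gA", "c1", "+", 2000L, rbind(c(2000L, 3000L)))
  gB <- gene_model("gB", "c1", "+", 2500L, rbind(c(2500L, 2600L)))
  sites <- data.frame(chrom = "c1",
                      pos = c(2300L,  # in gA span and gB promoter only
                              2990L,  # in gA span only
                              9000L), # nowhere
                      strand = "+")
  a <- assign_site_genes(sites, list(gA, gB))
  expect_equal(a[1], "gB")  # promoter owner wins over host gene
  expect_equal(a[2], "gA")
  expect_true(is.na(a[3]))
})

test_that("site-level correlations run per assigned site", {
  sim <- study_sim()
  fmat <- apply_site_filter(sim$matrix)
  sub <- subset_matrix(fmat, sites = 1:400)
  assign <- assign_site_genes(sub$sites, sim$genes)
  res <- site_expression_correlation(sub, assign, sim$expr)
  expect_true(all(res$rho >= -1 & res$rho <= 1))
  expect_true(all(res$gene_id %in% rownames(sim$expr)))
  expect_equal(attr(res, "n_unassigned") + nrow(res) +
                 sum(!is.na(assign) & !(assign %in% rownames(sim$expr))),
               400)
})
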