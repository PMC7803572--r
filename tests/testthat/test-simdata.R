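test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 5, chrom_length = 30000, n_genes = 4,
                    cgi_per_chrom = 2, n_tissue_dmc = 20, n_age_dmc = 10,
                    n_breed_dmc = 10, n_sex_dmc = 5,
                    n_pedigree_windows = 1, n_coupled_genes = 2)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(as.character(a$genome$seqs), as.character(b$genome$seqs))
  expect_identical(a$matrix$meth, b$matrix$meth)
  expect_identical(a$matrix$total, b$matrix$total)
  expect_identical(a$expr, b$expr)
  # a different seed changes the data
  c <- simulate_study(sim_config(seed = 6, chrom_length = 30000,
                                 n_genes = 4, cgi_per_chrom = 2,
                                 n_tissue_dmc = 20, n_age_dmc = 10,
                                 n_breed_dmc = 10, n_sex_dmc = 5,
                                 n_pedigree_windows = 1,
                                 n_coupled_genes = 2))
  expect_false(identical(a$matrix$meth, c$matrix$meth))
})

test_that("the pedigree mirrors the 20-sample study design", {
  sheet <- simulate_pedigree(sim_config())
  expect_equal(nrow(sheet), 20)
  expect_equal(sum(sheet$tissue == "muscle"), 12)
  expect_equal(sum(sheet$tissue == "testis"), 8)
  bmx <- unique(sheet[sheet$breed == "BMX",
                      c("individual_id", "age_years")])
  expect_equal(sort(table(bmx$age_years), decreasing = TRUE),
               sort(table(c(9, 9, 9, 4, 4, 4, 1, 1)), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(sum(sheet$breed == "LW" & sheet$tissue == "muscle"), 4)
  # testis only from males
  expect_true(all(sheet$sex[sheet$tissue == "testis"] == "M"))
  # offspring sires resolve within the recorded individuals
  kids <- sheet[!is.na(sheet$sire_id) & sheet$breed == "BMX", ]
  expect_true(any(kids$sire_id %in% sheet$individual_id))
})

test_that("planted islands satisfy the detection criterion in isolation", {
  sim <- study_sim()
  for (i in seq_len(nrow(sim$cgis))) {
    seq <- substr(chrom_seq(sim$genome, sim$cgis$chrom[i]),
                  sim$cgis$start[i] + 1L, sim$cgis$end[i])
    expect_gt(nchar(seq), 200)
    expect_gt(gc_fraction(seq), 0.5)
    expect_gt(obs_exp_ratio(seq), 0.6)
  }
  # zero-island config gives a background-only genome
  g0 <- simulate_genome(sim_config(cgi_per_chrom = 0, n_genes = 4,
                                   tss_in_cgi_frac = 0))
  expect_equal(nrow(g0$cgis), 0)
})

test_that("every planted site exists in the simulated matrix", {
  sim <- study_sim()
  keys <- site_key(sim$matrix$sites)
  for (tab in sim$truth[c("tissue", "age", "breed", "sex",
                          "pedigree_sites")]) {
    expect_true(all(site_key(tab) %in% keys))
  }
  # planted effects imply level differences of at least 0.3
  expect_true(all(sim$truth$tissue$level_diff >= 0.3))
})

test_that("planted tissue effects separate observed group means", {
  sim <- study_sim()
  lv <- meth_levels(sim$matrix)
  tk <- site_key(sim$truth$tissue)
  idx <- match(tk, site_key(sim$matrix$sites))
  tis <- sim$samples$tissue[match(sim$matrix$samples,
                                  sim$samples$sample_id)]
  diff <- rowMeans(lv[idx, tis == "testis"], na.rm = TRUE) -
    rowMeans(lv[idx, tis == "muscle"], na.rm = TRUE)
  signed <- diff * sign(sim$truth$tissue$delta_logit)
  # most planted sites show the planted direction at a usable magnitude
  expect_gt(mean(signed > 0.2), 0.85)
})

test_that("the binomial limit has no extra-binomial noise", {
  cfg <- sim_config(seed = 3, sigma2 = 0, bb_concentration = Inf,
                    n_tissue_dmc = 0, n_age_dmc = 0, n_breed_dmc = 0,
                    n_sex_dmc = 0, n_pedigree_windows = 0,
                    n_coupled_genes = 0, chrom_length = 30000,
                    cgi_per_chrom = 2, n_genes = 4)
  sim <- simulate_study(cfg)
  lv <- meth_levels(sim$matrix)
  # overall mean near the mixture mean implied by the config
  expect_equal(mean(lv, na.rm = TRUE), 0.7, tolerance = 0.06)
  # per-site across-sample variance should match binomial sampling noise:
  # compare observed to expected binomial variance of the level
  p <- rowMeans(lv, na.rm = TRUE)
  vobs <- apply(lv, 1, var, na.rm = TRUE)
  vexp <- p * (1 - p) / rowMeans(sim$matrix$total, na.rm = TRUE)
  mid <- p > 0.2 & p < 0.8
  expect_equal(median(vobs[mid] / vexp[mid]), 1, tolerance = 0.25)
})

test_that("expression coupling follows the configured slopes and signs", {
  sim <- study_sim()
  truth <- sim$expr_truth
  pmm <- sim$truth$promoter_meth
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_id[i]
    r <- cor(pmm[g, ], log1p(sim$expr[g, ]), method = "spearman")
    expect_gt(r * truth$sign[i], 0.5)
  }
  # noise-free strong negative coupling gives rho = -1 exactly
  cfg0 <- sim_config(seed = 4, expression_noise_sd = 0,
                     coupling_slope = 5)
  pm <- matrix(seq(0.1, 0.9, length.out = 12), 1, 12,
               dimnames = list("gX", paste0("s", 1:12)))
  genes <- list(gene_model("gX", "c1", "+", 0L, rbind(c(0L, 100L))))
  ex <- simulate_expression(genes, pm, cfg0, coupled = "gX")
  rho <- cor(pm["gX", ], ex$expr["gX", ], method = "spearman")
  expect_equal(abs(rho), 1)
  # requesting a coupled gene without promoter CpGs names it
  expect_error(simulate_expression(genes, pm, cfg0,
                                   coupled = c("gX", "gMissing")),
               "gMissing")
})

test_that("null coupling yields correlations centred at zero", {
  cfg <- sim_config(seed = 8, coupling_slope = 0)
  pm <- matrix(runif(5 * 20), 5, 20,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  genes <- lapply(paste0("g", 1:5), function(id)
    gene_model(id, "c1", "+", 0L, rbind(c(0L, 100L))))
  ex <- simulate_expression(genes, pm, cfg)
  rhos <- vapply(paste0("g", 1:5), function(g)
    cor(pm[g, ], ex$expr[g, ], method = "spearman"), numeric(1))
  expect_lt(max(abs(rhos)), 0.7)
  expect_lt(abs(mean(rhos)), 0.35)
})

test_that("infeasible genome configurations are rejected", {
  expect_error(sim_config(chrom_length = 4000), "10x")
  expect_error(simulate_genome(sim_config(chrom_length = 30000,
                                          cgi_per_chrom = 20)),
               "infeasible")
  bad <- sim_config()
  bad$sigma2 <- -1
  expect_error(simulate_methylomes(study_sim()$genome, study_sim()$cgis,
                                   simulate_pedigree(sim_config()), bad),
               "sigma2")
})
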