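# Monte-Carlo oracle for the posterior probability of a small difference.
mc_mindiff <- function(a1, b1, a2, b2, delta, n = 1e6, seed = 202) {
  set.seed(seed)
  mean(abs(rbeta(n, a1, b1) - rbeta(n, a2, b2)) < delta)
}

test_that("beta posterior shapes and means follow the conjugate update", {
  p <- beta_posterior(5, 5)
  expect_equal(c(p$alpha, p$beta, p$mean), c(6, 6, 0.5))
  p0 <- beta_posterior(0, 0)
  expect_equal(c(p0$alpha, p0$beta, p0$mean), c(1, 1, 0.5))
  p1 <- beta_posterior(100, 0)
  expect_equal(c(p1$alpha, p1$beta), c(101, 1))
  expect_equal(p1$mean, 101 / 102)
  expect_error(beta_posterior(-1, 0), "non-negative")
})

test_that("minimum-difference test agrees with a Monte-Carlo oracle", {
  # extreme separation: near-certain difference
  r <- posterior_mindiff_test(200, 200, 0, 200)
  expect_lt(r$p_small, 1e-6)
  expect_true(r$is_dmc)
  expect_equal(r$direction, "down")
  expect_equal(r$p_small, mc_mindiff(201, 1, 1, 201, 0.3),
               tolerance = 1e-3)
  # identical posteriors: difference concentrated near 0
  r2 <- posterior_mindiff_test(50, 100, 50, 100)
  expect_gt(r2$p_small, 0.99)
  expect_false(r2$is_dmc)
  # low coverage: wide posteriors, not callable
  r3 <- posterior_mindiff_test(3, 4, 1, 4)
  expect_gt(r3$p_small, 0.01)
  expect_false(r3$is_dmc)
  expect_equal(r3$p_small, mc_mindiff(4, 2, 2, 4, 0.3), tolerance = 1e-3)
  expect_error(posterior_mindiff_test(integer(), integer(), integer(),
                                      integer()), "empty")
})

test_that("minimum-difference test is exactly symmetric in its groups", {
  cases <- list(c(30, 40, 5, 50), c(200, 210, 190, 200), c(3, 9, 7, 9))
  for (cs in cases) {
    r1 <- posterior_mindiff_test(cs[1], cs[2], cs[3], cs[4])
    r2 <- posterior_mindiff_test(cs[3], cs[4], cs[1], cs[2])
    expect_lte(abs(r1$p_small - r2$p_small), 1e-12)
    expect_equal(r1$level_diff, -r2$level_diff)
    if (r1$level_diff != 0)
      expect_false(r1$direction == r2$direction)
  }
})

test_that("positive rate is monotone in delta and in alpha", {
  sim <- study_sim()
  m <- apply_site_filter(subset_matrix(sim$matrix, sites = 1:800))
  sheet <- sim$samples
  rates_d <- vapply(c(0.1, 0.3, 0.5), function(d) {
    r <- dmc_scan(m, sheet, "tissue", method = "mindiff", delta = d,
                  keep_all = TRUE)
    mean(r$is_dmc, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(rates_d) <= 0))
  r <- dmc_scan(m, sheet, "tissue", method = "mindiff", keep_all = TRUE)
  rates_a <- vapply(c(0.001, 0.01, 0.1),
                    function(a) mean(r$p_value <= a, na.rm = TRUE),
                    numeric(1))
  expect_true(all(diff(rates_a) >= 0))
})

test_that("DMR merging equals brute-force transitive closure", {
  # worked example: 100, 400, 1200 with gap 500
  d <- data.frame(chrom = "c1", pos = c(100L, 400L, 1200L),
                  direction = c("up", "up", "down"))
  r <- merge_dmrs(d, gap = 500)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(100L, 1200L))
  expect_equal(r$end, c(401L, 1201L))
  expect_equal(r$n_up, c(2L, 0L))
  # empty input
  expect_equal(nrow(merge_dmrs(d[0, ])), 0)
  # brute force on 1000 random sites across chromosomes
  set.seed(33)
  pos <- sample(1:50000, 1000)
  chrom <- sample(c("c1", "c2"), 1000, replace = TRUE)
  d2 <- data.frame(chrom = chrom, pos = pos,
                   direction = sample(c("up", "down"), 1000, TRUE))
  got <- merge_dmrs(d2, gap = 500)
  # oracle: transitive closure by pairwise linking, per chromosome
  oracle <- do.call(rbind, lapply(sort(unique(d2$chrom)), function(ch) {
    p <- sort(d2$pos[d2$chrom == ch])
    grp <- cumsum(c(TRUE, diff(p) > 500))
    data.frame(chrom = ch,
               start = vapply(split(p, grp), min, numeric(1)),
               end = vapply(split(p, grp), max, numeric(1)) + 1,
               n = lengths(split(p, grp)))
  }))
  got <- got[order(got$chrom, got$start), ]
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(got$start, as.integer(oracle$start))
  expect_equal(got$end, as.integer(oracle$end))
  expect_equal(got$n_sites, as.integer(oracle$n))
  # member sites are conserved
  expect_equal(sum(got$n_sites), 1000)
  # idempotent under permutation of input rows
  got2 <- merge_dmrs(d2[sample(1000), ], gap = 500)
  got2 <- got2[order(got2$chrom, got2$start), ]
  expect_equal(got2$start, got$start)
})

test_that("promoter DMR screening needs overlap and synclastic support", {
  dmrs <- data.frame(chrom = "c1", start = c(100L, 600L, 5000L),
                     end = c(300L, 900L, 5100L),
                     n_sites = c(7L, 6L, 8L),
                     n_up = c(5L, 3L, 8L), n_down = c(2L, 3L, 0L))
  regions <- region_set("c1", c(0L, 550L), c(400L, 1000L), "screen")
  regions$gene_id <- c("gA", "gB")
  kept <- screen_promoter_dmrs(dmrs, regions, min_synclastic = 5)
  # first: 5 up, overlapping -> kept; second: 3/3 -> dropped;
  # third: no overlap -> dropped
  expect_equal(nrow(kept), 1)
  expect_equal(kept$gene_id, "gA")
})

test_that("pairwise age scans find planted trends with correct direction", {
  sim <- study_sim()
  bmx <- subset_breed(apply_site_filter(sim$matrix), sim$samples, "BMX")
  tk <- site_key(sim$truth$age)
  idx <- match(tk, site_key(bmx$sites))
  keep <- sort(idx[!is.na(idx)])
  set.seed(9)
  extra <- sort(sample(setdiff(seq_len(n_sites(bmx)), keep), 300))
  sub <- subset_matrix(bmx, sites = sort(c(keep, extra)))
  scan <- pairwise_age_scan(sub, sim$samples)
  expect_true(any(grepl("9v1", names(scan$results))))
  r91 <- scan$results[["muscle:9v1"]]
  isp <- site_key(r91) %in% tk
  # planted monotone trends are detected in the widest comparison at a
  # rate far above the (near-zero) null rate
  expect_gt(mean(r91$is_dmc[isp], na.rm = TRUE), 0.25)
  expect_lt(mean(r91$is_dmc[!isp], na.rm = TRUE), 0.02)
  # detection grows with the age gap (9v1 sees more than 4v1)
  r41 <- scan$results[["muscle:4v1"]]
  expect_gt(mean(r91$is_dmc[isp], na.rm = TRUE),
            mean(r41$is_dmc[site_key(r41) %in% tk], na.rm = TRUE))
  # directions match the planted slope sign (group B = older)
  tdir <- sim$truth$age$direction[match(site_key(r91)[isp], tk)]
  hit <- r91$is_dmc[isp]
  expect_gt(mean(r91$direction[isp][hit] == tdir[hit]), 0.95)
  # a tissue with a single age group is skipped, not fatal
  one_age <- sim$samples[sim$samples$tissue == "muscle" &
                           sim$samples$age_years == 4, ]
  m2 <- subset_matrix(sub, samples = one_age$sample_id)
  scan2 <- pairwise_age_scan(m2, one_age)
  expect_length(scan2$results, 0)
  expect_gt(length(scan2$skipped), 0)
})
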