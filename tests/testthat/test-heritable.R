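# Independent oracle: binomial upper tail by explicit pmf summation with
# choose(), never via pbinom.
enum_tail <- function(N, size, prob) {
  if (N > size) return(0)
  k <- N:size
  sum(choose(size, k) * prob^k * (1 - prob)^(size - k))
}

test_that("expected CpG count follows (#C x #G)/L", {
  expect_equal(expected_cpg_count(125, 125, 500), 31.25)
  expect_equal(round(expected_cpg_count(125, 125, 500)), 31)
  expect_equal(expected_cpg_count(0, 50, 500), 0)
  expect_equal(expected_cpg_count(4, 4, 16), 1)
  expect_error(expected_cpg_count(1, 1, 0), "positive")
})

test_that("pfp reproduces the worked genome-wide bound", {
  expect_equal(round(pfp(5, 31, 0.003, 2.5e9, 500), 3), 0.012)
  # before rounding the exact tail is close to 0.0125
  expect_equal(pfp(5, 31, 0.003, 2.5e9, 500), 0.01249, tolerance = 1e-3)
  # N = 0: the tail is the whole support
  expect_equal(pfp(0, 31, 0.003, 2.5e9, 500), 2 * 2.5e9 / 500)
  # N beyond the support
  expect_equal(pfp(40, 31, 0.003, 2.5e9, 500), 0)
  expect_error(pfp(-1, 31, 0.003, 2.5e9, 500), "non-negative")
  expect_error(pfp(5, 31, 2.5, 2.5e9, 500), "p/2")
})

test_that("pfp equals brute-force enumeration including large p", {
  # hand-checkable case: ECG = 4, p = 0.999 -> q ~ 0.4995
  q <- 0.999 / 2
  manual <- 1 - (1 - q)^4 - 4 * q * (1 - q)^3
  expect_equal(pfp(2, 4, 0.999, 1000, 500), 2 * manual * 2,
               tolerance = 1e-12)
  # grid agreement with exhaustive summation
  for (p in c(0.001, 0.01, 0.1)) {
    for (ecg in c(5, 17, 50)) {
      for (N in c(0, 2, 5, min(ecg, 20))) {
        got <- pfp(N, ecg, p, 1e6, 500)
        want <- 2 * enum_tail(N, round(ecg), p / 2) * 1e6 / 500
        if (want > 0) expect_equal(got, want, tolerance = 1e-12)
        else expect_equal(got, 0)
      }
    }
  }
})

test_that("pfp is monotone in N, p, ECG and GS", {
  Ns <- 1:10
  vals <- vapply(Ns, function(N) pfp(N, 31, 0.003, 2.5e9, 500), numeric(1))
  expect_true(all(diff(vals) < 0))
  ps <- c(0.001, 0.003, 0.01, 0.1)
  vp <- vapply(ps, function(p) pfp(5, 31, p, 2.5e9, 500), numeric(1))
  expect_true(all(diff(vp) > 0))
  ve <- vapply(c(10, 20, 31, 45), function(e) pfp(5, e, 0.003, 2.5e9, 500),
               numeric(1))
  expect_true(all(diff(ve) > 0))
  vg <- vapply(c(1e8, 1e9, 2.5e9), function(g) pfp(5, 31, 0.003, g, 500),
               numeric(1))
  expect_true(all(diff(vg) > 0))
})

test_that("pedigree DMC calls require pooled evidence and consistency", {
  # 8 testis-like samples, 4 per pedigree, coverage 30
  sheet <- data.frame(sample_id = paste0("t", 1:8),
                      individual_id = paste0("i", 1:8),
                      tissue = "testis", breed = "B", age_years = 4,
                      sex = "M",
                      pedigree_id = rep(c("pA", "pB"), each = 4),
                      sire_id = NA, dam_id = NA)
  sites <- data.frame(chrom = "c1", pos = c(10L, 20L, 30L), strand = "+")
  # site 1: clean separation 0.9 vs 0.1; site 2: one pA sample at 0.1
  # breaks consistency; site 3: no difference
  meth <- rbind(c(27L, 28L, 26L, 27L, 3L, 2L, 4L, 3L),
                c(27L, 28L, 26L, 3L, 3L, 2L, 4L, 3L),
                c(15L, 14L, 16L, 15L, 15L, 14L, 16L, 15L))
  total <- matrix(30L, 3, 8)
  m <- meth_count_matrix(sites, sheet$sample_id, meth, total)
  pd <- pedigree_dmc(m, sheet, tissue = "testis")
  expect_equal(pd$is_dmc, c(TRUE, FALSE, FALSE))
  expect_equal(pd$consistent, c(TRUE, FALSE, FALSE))
  # rule (i) alone passes for site 2 (pooled difference is large)
  expect_true(pd$p_small[2] <= 0.01)
  # a single pedigree is an error
  solo <- sheet[sheet$pedigree_id == "pA", ]
  expect_error(pedigree_dmc(subset_matrix(m, samples = solo$sample_id),
                            solo, tissue = "testis"), "two pedigrees")
})

test_that("window scan composes merging, ECG and pfp correctly", {
  # composition identity: with p overridden, a window's p_fp must match
  # pfp() on its own N and ECG
  sim <- study_sim()
  fmat <- apply_site_filter(sim$matrix)
  pd <- pedigree_dmc(fmat, sim$samples, tissue = "testis",
                     pedigrees = c("ped1", "ped2"))
  hw <- scan_heritable_windows(pd, sim$genome,
                               heritable_params(p = 0.003))
  expect_gt(nrow(hw), 0)
  for (i in seq_len(nrow(hw))) {
    span <- max(500, hw$end[i] - hw$start[i])
    expect_equal(hw$p_fp[i],
                 pfp(hw$N[i], hw$ECG[i], 0.003, sim$genome$GS, span),
                 tolerance = 1e-12)
  }
  # windows below min_N are never reported
  strict <- scan_heritable_windows(pd, sim$genome,
                                   heritable_params(min_N = 100))
  expect_equal(nrow(strict), 0)
})

test_that("planted pedigree windows are reported and null scans are empty", {
  sim <- study_sim()
  fmat <- apply_site_filter(sim$matrix)
  pd <- pedigree_dmc(fmat, sim$samples, tissue = "testis",
                     pedigrees = c("ped1", "ped2"))
  hw <- scan_heritable_windows(pd, sim$genome)
  truth <- sim$truth$pedigree_windows
  expect_equal(nrow(truth), 2)
  for (i in seq_len(nrow(truth))) {
    ov <- hw[hw$chrom == truth$chrom[i] & hw$start < truth$end[i] &
               hw$end > truth$start[i], ]
    expect_equal(nrow(ov), 1)
    expect_lte(ov$p_fp, 0.01)
    expect_gte(ov$N, 14)
  }
  # null data: no planted windows -> no reported windows
  nsim <- null_sim()
  nf <- apply_site_filter(nsim$matrix)
  npd <- pedigree_dmc(nf, nsim$samples, tissue = "testis",
                      pedigrees = c("ped1", "ped2"))
  nhw <- scan_heritable_windows(npd, nsim$genome)
  expect_equal(nrow(nhw), 0)
})
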