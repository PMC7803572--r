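# Beta-posterior minimum-difference testing, DMC scanning, and DMR
# construction.

#' Beta posterior of a methylation level
#'
#' With a Beta(a0, b0) prior and counts (m methylated, u unmethylated), the
#' posterior is Beta(m + a0, u + b0). The default uniform prior gives
#' posterior mean (m + 1) / (m + u + 2), which shrinks low-coverage sites
#' toward 0.5 and thereby corrects the effect of sequencing depth on the
#' level estimate.
#'
#' @param m,u Non-negative integer counts (vectorized).
#' @param prior Length-2 prior shape `(a0, b0)`, default `c(1, 1)`.
#' @return List with vectors `alpha`, `beta`, `mean`.
#' @export
beta_posterior <- function(m, u, prior = c(1, 1)) {
  if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  stopifnot(length(prior) == 2, all(prior > 0))
  a <- m + prior[1]; b <- u + prior[2]
  list(alpha = a, beta = b, mean = a / (a + b))
}

# P(|thetaA - thetaB| < delta) for beta posteriors, by deterministic
# Gauss-Legendre quadrature in the probability transform of each posterior
# (handles arbitrarily spiky posteriors). Symmetrized over the two
# orientations so that swapping groups is an exact identity. Vectorized
# over sites.
.mindiff_prob <- function(a1, b1, a2, b2, delta, grid_n = 512) {
  gl <- pracma::gaussLegendre(grid_n, 0, 1)
  acc <- numeric(length(a1))
  for (k in seq_len(grid_n)) {
    q1 <- stats::qbeta(gl$x[k], a1, b1)
    acc <- acc + gl$w[k] *
      (stats::pbeta(pmin(q1 + delta, 1), a2, b2) -
         stats::pbeta(pmax(q1 - delta, 0), a2, b2))
    q2 <- stats::qbeta(gl$x[k], a2, b2)
    acc <- acc + gl$w[k] *
      (stats::pbeta(pmin(q2 + delta, 1), a1, b1) -
         stats::pbeta(pmax(q2 - delta, 0), a1, b1))
  }
  pmin(pmax(acc / 2, 0), 1)
}

#' Beta-posterior minimum-difference test
#'
#' Pools counts within each group, forms the two beta posteriors, and
#' computes `P_small`, the posterior probability that the absolute level
#' difference is below `delta`. A site is a DMC when `P_small <= alpha`,
#' i.e. when the posterior puts at least `1 - alpha` mass on a difference
#' of `delta` or more.
#'
#' @param meth_a,total_a Counts for group A (vectors over samples; `NA`
#'   cells ignored).
#' @param meth_b,total_b Counts for group B.
#' @param delta Minimum level difference (default 0.3).
#' @param alpha Significance level on `P_small` (default 0.01).
#' @param grid_n Quadrature size (default 512).
#' @param prior Beta prior.
#' @return List: `p_small`, `is_dmc`, `direction` (`"up"` if group B's
#'   posterior mean exceeds group A's, else `"down"`), `level_diff`
#'   (posterior mean B minus A), posterior means `mean_a`, `mean_b`.
#' @export
posterior_mindiff_test <- function(meth_a, total_a, meth_b, total_b,
                                   delta = 0.3, alpha = 0.01, grid_n = 512,
                                   prior = c(1, 1)) {
  ma <- sum(meth_a, na.rm = TRUE); ta <- sum(total_a, na.rm = TRUE)
  mb <- sum(meth_b, na.rm = TRUE); tb <- sum(total_b, na.rm = TRUE)
  if ((all(is.na(total_a)) || length(total_a) == 0) &&
      (all(is.na(total_b)) || length(total_b) == 0))
    stop("both groups are empty")
  pa <- beta_posterior(ma, ta - ma, prior)
  pb <- beta_posterior(mb, tb - mb, prior)
  p_small <- .mindiff_prob(pa$alpha, pa$beta, pb$alpha, pb$beta, delta,
                           grid_n)
  diff <- pb$mean - pa$mean
  list(p_small = p_small, is_dmc = p_small <= alpha,
       direction = if (diff >= 0) "up" else "down",
       level_diff = diff, mean_a = pa$mean, mean_b = pb$mean)
}

# Vectorized group scan of the minimum-difference test over all sites of a
# matrix. Returns a full per-site table.
.mindiff_scan <- function(mat, idx_a, idx_b, delta, alpha, grid_n = 512,
                          prior = c(1, 1)) {
  sum_rows <- function(x, idx) {
    x <- x[, idx, drop = FALSE]
    rowSums(x, na.rm = TRUE)
  }
  has <- function(idx) rowSums(!is.na(mat$total[, idx, drop = FALSE])) > 0
  ma <- sum_rows(mat$meth, idx_a); ta <- sum_rows(mat$total, idx_a)
  mb <- sum_rows(mat$meth, idx_b); tb <- sum_rows(mat$total, idx_b)
  ok <- has(idx_a) & has(idx_b)
  pa <- beta_posterior(ma, ta - ma, prior)
  pb <- beta_posterior(mb, tb - mb, prior)
  p_small <- rep(NA_real_, length(ma))
  if (any(ok))
    p_small[ok] <- .mindiff_prob(pa$alpha[ok], pa$beta[ok], pb$alpha[ok],
                                 pb$beta[ok], delta, grid_n)
  diff <- pb$mean - pa$mean
  data.frame(mat$sites,
             p_small = p_small,
             is_dmc = !is.na(p_small) & p_small <= alpha,
             direction = ifelse(diff >= 0, "up", "down"),
             level_diff = diff, mean_a = pa$mean, mean_b = pb$mean,
             stringsAsFactors = FALSE)
}

#' Merge DMC sites into DMRs
#'
#' Consecutive differential sites on one chromosome whose inter-site
#' distance is at most `gap` are combined into one region (transitive
#' closure); singleton regions are allowed. Direction counts (`n_up`,
#' `n_down`) are recorded per region.
#'
#' @param dmc `data.frame` with columns `chrom`, `pos` and optionally
#'   `direction` (`"up"`/`"down"`).
#' @param gap Maximum merge distance in bp (default 500).
#' @return `data.frame`: `chrom`, `start`, `end` (0-based half-open span of
#'   member cytosines), `n_sites`, `n_up`, `n_down`.
#' @export
merge_dmrs <- function(dmc, gap = 500) {
  if (nrow(dmc) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      n_up = integer(), n_down = integer()))
  if (!"direction" %in% names(dmc)) dmc$direction <- NA_character_
  dmc <- dmc[order(dmc$chrom, dmc$pos, method = "radix"), , drop = FALSE]
  new_chrom <- c(TRUE, dmc$chrom[-1] != dmc$chrom[-nrow(dmc)])
  big_gap <- c(TRUE, diff(dmc$pos) > gap)
  grp <- cumsum(new_chrom | big_gap)
  out <- do.call(rbind, lapply(split(seq_len(nrow(dmc)), grp), function(i) {
    data.frame(chrom = dmc$chrom[i[1]],
               start = min(dmc$pos[i]),
               end = max(dmc$pos[i]) + 1L,
               n_sites = length(i),
               n_up = sum(dmc$direction[i] == "up", na.rm = TRUE),
               n_down = sum(dmc$direction[i] == "down", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Screen DMRs overlapping promoter regions with enough synclastic DMCs
#'
#' Keeps DMRs that overlap a screening region and contain at least
#' `min_synclastic` same-direction member DMCs
#' (`max(n_up, n_down) >= min_synclastic`).
#'
#' @param dmrs Output of [merge_dmrs()].
#' @param regions `RegionSet` of promoter/first-exon screening regions
#'   (see [dmr_screen_regions()]).
#' @param min_synclastic Minimum count of same-direction DMCs (default 5).
#' @return Subset of `dmrs` with a `gene_id` column (comma-separated when a
#'   DMR touches several genes).
#' @export
screen_promoter_dmrs <- function(dmrs, regions, min_synclastic = 5) {
  if (nrow(dmrs) == 0 || nrow(regions) == 0)
    return(cbind(dmrs[0, , drop = FALSE], gene_id = character()))
  syn <- pmax(dmrs$n_up, dmrs$n_down) >= min_synclastic
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start + 1L,
                                                    dmrs$end))
  reg_gr <- .regions_to_granges(regions)
  ov <- GenomicRanges::findOverlaps(dmr_gr, reg_gr)
  hit <- logical(nrow(dmrs))
  genes <- character(nrow(dmrs))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    gid <- if ("gene_id" %in% names(regions)) regions$gene_id else
      regions$label
    by_dmr <- split(gid[S4Vectors::subjectHits(ov)], qh)
    hit[as.integer(names(by_dmr))] <- TRUE
    genes[as.integer(names(by_dmr))] <-
      vapply(by_dmr, function(g) paste(unique(g), collapse = ","), "")
  }
  keep <- syn & hit
  out <- dmrs[keep, , drop = FALSE]
  out$gene_id <- genes[keep]
  rownames(out) <- NULL
  out
}

#' Pairwise age-group scans within tissues
#'
#' For every tissue, runs the beta-posterior minimum-difference test between
#' each ordered pair of age groups (older vs younger; e.g. 9v1, 9v4, 4v1)
#' and reports per-site direction with age (`"up"` = hypermethylated with
#' age) plus the sites shared across tissues per pair.
#'
#' @param mat A filtered `MethCountMatrix`.
#' @param samples Sample sheet covering the matrix columns.
#' @param delta,alpha,grid_n Test parameters.
#' @param min_per_group Minimum samples per age group; pairs lacking it are
#'   skipped with a message.
#' @return List: `results` (named `"<tissue>:<old>v<young>"` -> DMC
#'   `data.frame`), `shared` (per pair, sites differential in every tissue
#'   scanned for that pair), `skipped` (character vector of skipped pairs).
#' @export
pairwise_age_scan <- function(mat, samples, delta = 0.3, alpha = 0.01,
                              grid_n = 512, min_per_group = 2) {
  samples <- samples[match(mat$samples, samples$sample_id), ]
  results <- list(); skipped <- character()
  for (tissue in unique(samples$tissue)) {
    in_tissue <- samples$tissue == tissue
    ages <- sort(unique(samples$age_years[in_tissue]), decreasing = TRUE)
    if (length(ages) < 2) {
      skipped <- c(skipped, paste0(tissue, ": <2 age groups"))
      next
    }
    for (i in seq_along(ages)) for (j in seq_along(ages)) {
      if (j <= i) next
      old <- ages[i]; young <- ages[j]
      idx_old <- which(in_tissue & samples$age_years == old)
      idx_young <- which(in_tissue & samples$age_years == young)
      key <- sprintf("%s:%gv%g", tissue, old, young)
      if (length(idx_old) < min_per_group ||
          length(idx_young) < min_per_group) {
        message("pairwise_age_scan: pair ", key, " skipped (too few samples)")
        skipped <- c(skipped, key)
        next
      }
      # group A = young, group B = old: "up" = hypermethylated with age
      results[[key]] <- .mindiff_scan(mat, idx_young, idx_old, delta,
                                      alpha, grid_n)
    }
  }
  shared <- list()
  pairs <- unique(sub("^[^:]+:", "", names(results)))
  for (pr in pairs) {
    members <- results[grepl(paste0(":", pr, "$"), names(results))]
    if (length(members) < 2) next
    keys <- lapply(members, function(r)
      paste(r$chrom, r$pos, r$strand)[r$is_dmc])
    common <- Reduce(intersect, keys)
    r1 <- members[[1]]
    sel <- paste(r1$chrom, r1$pos, r1$strand) %in% common
    shared[[pr]] <- r1[sel, c("chrom", "pos", "strand", "direction")]
  }
  list(results = results, shared = shared, skipped = skipped)
}
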