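# Coverage filtering, methylation levels, global summaries, hypo/hyper
# classification and 2x2 enrichment tests.

#' Site filter policy
#'
#' A cell passes when its total coverage lies in `[min_cov, max_cov]`; a
#' site is retained when the number of passing cells is at least
#' `ceiling(min_presence_fraction * n_samples)`. Non-passing cells of
#' retained sites are masked missing.
#'
#' @param min_cov Minimum coverage (default 10).
#' @param max_cov Maximum coverage (default 300).
#' @param min_presence_fraction Fraction of samples that must pass
#'   (default 0.5).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_cov = 10, max_cov = 300,
                          min_presence_fraction = 0.5) {
  stopifnot(min_cov > 0, min_cov <= max_cov,
            min_presence_fraction > 0, min_presence_fraction <= 1)
  structure(list(min_cov = min_cov, max_cov = max_cov,
                 min_presence_fraction = min_presence_fraction),
            class = "filter_policy")
}

#' Apply a coverage filter to a MethCountMatrix
#'
#' @param mat A `MethCountMatrix`.
#' @param policy A [filter_policy()].
#' @return Filtered `MethCountMatrix` with attributes `n_dropped_sites` and
#'   `n_masked_cells`.
#' @export
apply_site_filter <- function(mat, policy = filter_policy()) {
  pass <- !is.na(mat$total) & mat$total >= policy$min_cov &
    mat$total <= policy$max_cov
  need <- ceiling(policy$min_presence_fraction * length(mat$samples))
  keep <- rowSums(pass) >= need
  if (!any(keep)) warning("no sites pass the coverage filter")
  meth <- mat$meth[keep, , drop = FALSE]
  total <- mat$total[keep, , drop = FALSE]
  mask <- !pass[keep, , drop = FALSE]
  n_masked <- sum(mask & !is.na(total))
  meth[mask] <- NA_integer_; total[mask] <- NA_integer_
  out <- meth_count_matrix(mat$sites[keep, , drop = FALSE], mat$samples,
                           meth, total)
  attr(out, "n_dropped_sites") <- sum(!keep)
  attr(out, "n_masked_cells") <- n_masked
  out
}

#' Methylation level of a count pair
#' @param meth,total Non-negative counts; `total` must be >= 1 (callers
#'   treat zero-coverage cells as missing).
#' @return `meth / total`.
#' @export
methylation_level <- function(meth, total) {
  if (any(total < 1, na.rm = TRUE))
    stop("methylation level undefined for total < 1; treat as missing")
  meth / total
}

#' Per-cell methylation levels of a matrix
#' @param mat A `MethCountMatrix`.
#' @return Numeric matrix of levels with `NA` for missing cells.
#' @export
meth_levels <- function(mat) {
  mat$meth / mat$total
}

.binary_entropy <- function(l) {
  h <- numeric(length(l))
  inner <- !is.na(l) & l > 0 & l < 1
  h[inner] <- -(l[inner] * log2(l[inner]) +
                  (1 - l[inner]) * log2(1 - l[inner]))
  h[is.na(l)] <- NA
  h
}

#' Global per-sample methylation summaries
#'
#' Per-sample mean level (over non-missing cells), per-sample mean binary
#' entropy (bits), a pooled level histogram, and optional one-way ANOVA of
#' both summaries across supplied groups.
#'
#' @param mat A filtered `MethCountMatrix`.
#' @param groups Optional vector of group labels per sample.
#' @param breaks Histogram breaks on \[0,1\].
#' @return List with `sample_mean_level`, `sample_mean_entropy`,
#'   `histogram`, and when groups are supplied `anova_level_p` /
#'   `anova_entropy_p` (NA, with a warning, when any group has < 2 samples).
#' @export
global_stats <- function(mat, groups = NULL, breaks = seq(0, 1, by = 0.05)) {
  lv <- meth_levels(mat)
  mean_level <- colMeans(lv, na.rm = TRUE)
  ent <- matrix(.binary_entropy(lv), nrow(lv), ncol(lv))
  mean_entropy <- colMeans(ent, na.rm = TRUE)
  names(mean_level) <- names(mean_entropy) <- mat$samples
  h <- graphics::hist(lv[!is.na(lv)], breaks = breaks, plot = FALSE)
  out <- list(sample_mean_level = mean_level,
              sample_mean_entropy = mean_entropy, histogram = h)
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (any(table(groups) < 2)) {
      warning("ANOVA skipped: some group has fewer than 2 samples")
      out$anova_level_p <- out$anova_entropy_p <- NA_real_
    } else {
      out$anova_level_p <-
        summary(stats::aov(mean_level ~ groups))[[1]][["Pr(>F)"]][1]
      out$anova_entropy_p <-
        summary(stats::aov(mean_entropy ~ groups))[[1]][["Pr(>F)"]][1]
    }
  }
  out
}

#' Classify sites as hypo-/hypermethylated
#'
#' Strict thresholds on the mean level across samples: hypomethylated below
#' `lo`, hypermethylated above `hi`, otherwise neither.
#'
#' @param mean_levels Numeric vector of per-site mean levels.
#' @param lo,hi Thresholds (defaults 0.10 and 0.90).
#' @return Factor (`hypo`, `hyper`, `neither`).
#' @export
classify_hypo_hyper <- function(mean_levels, lo = 0.10, hi = 0.90) {
  cls <- ifelse(is.na(mean_levels), NA,
         ifelse(mean_levels < lo, "hypo",
         ifelse(mean_levels > hi, "hyper", "neither")))
  factor(cls, levels = c("hypo", "hyper", "neither"))
}

#' Per-site mean methylation level
#' @param mat A `MethCountMatrix`.
#' @return Numeric vector: mean of per-sample levels over non-missing cells.
#' @export
site_mean_levels <- function(mat) {
  rowMeans(meth_levels(mat), na.rm = TRUE)
}

#' Fisher's exact 2x2 enrichment test
#'
#' Tests association between class membership and region membership. Both
#' the sample odds ratio `(a d)/(b c)` and the conditional-MLE odds ratio
#' from the exact test are reported; a zero margin yields `p = 1` and an
#' undefined odds ratio by convention.
#'
#' @param in_both Count in class and in region (a).
#' @param in_class_only Count in class, not in region (b).
#' @param in_region_only Count in region, not in class (c).
#' @param neither Count in neither (d).
#' @return List `or_sample`, `or_cmle`, `p`.
#' @export
enrichment_fisher <- function(in_both, in_class_only, in_region_only,
                              neither) {
  counts <- c(in_both, in_class_only, in_region_only, neither)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(or_sample = NA_real_, or_cmle = NA_real_, p = 1))
  }
  ft <- stats::fisher.test(tab)
  or_sample <- if (tab[1, 2] * tab[2, 1] == 0) Inf else
    tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  list(or_sample = or_sample, or_cmle = unname(ft$estimate), p = ft$p.value)
}
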