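# Promoter methylation-expression coupling: promoter means, Spearman
# correlations, and rank-based group expression tests.

#' Mean promoter methylation per gene and sample
#'
#' Unweighted mean of per-site levels over non-missing cells within each
#' gene's promoter window; genes with fewer than `min_cpgs` retained CpGs
#' in the window are dropped.
#'
#' @param mat A filtered `MethCountMatrix`.
#' @param promoters `RegionSet` from [promoter_windows()] (needs a
#'   `gene_id` column).
#' @param min_cpgs Minimum retained CpGs per promoter (default 10).
#' @return List: `meth` (gene x sample matrix of mean levels, `NA` when a
#'   sample has no observed promoter cell), `n_cpgs` (named vector),
#'   `dropped` (gene ids below the threshold).
#' @export
promoter_mean_methylation <- function(mat, promoters, min_cpgs = 10) {
  lv <- meth_levels(mat)
  site_gr <- GenomicRanges::GRanges(mat$sites$chrom,
                                    IRanges::IRanges(mat$sites$pos + 1L,
                                                     width = 1L))
  prom_gr <- .regions_to_granges(promoters)
  ov <- GenomicRanges::findOverlaps(site_gr, prom_gr)
  by_gene <- split(S4Vectors::queryHits(ov),
                   promoters$gene_id[S4Vectors::subjectHits(ov)])
  n_cpgs <- vapply(by_gene, length, integer(1))
  keep <- names(by_gene)[n_cpgs >= min_cpgs]
  dropped <- setdiff(promoters$gene_id, keep)
  m <- matrix(NA_real_, length(keep), length(mat$samples),
              dimnames = list(keep, mat$samples))
  for (g in keep) {
    sub <- lv[by_gene[[g]], , drop = FALSE]
    mm <- colMeans(sub, na.rm = TRUE)
    mm[is.nan(mm)] <- NA_real_
    m[g, ] <- mm
  }
  list(meth = m, n_cpgs = n_cpgs[keep], dropped = dropped)
}

#' Spearman correlation of methylation with expression
#'
#' Spearman's rho with average ranks for ties; the p-value uses the
#' t-distribution approximation `t = rho sqrt((n-2)/(1-rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param meth Numeric vector (e.g. promoter mean levels across samples).
#' @param expr Numeric vector of matching FPKM values.
#' @param alpha Significance threshold (default 0.01).
#' @return List: `rho`, `p_value`, `sign` (`"positive"`/`"negative"`),
#'   `n`, `significant`. Constant input yields `rho = NA` (flagged, not an
#'   error).
#' @export
spearman_methylation_expression <- function(meth, expr, alpha = 0.01) {
  ok <- !is.na(meth) & !is.na(expr)
  n <- sum(ok)
  if (n < 5) stop("need at least 5 complete pairs")
  x <- meth[ok]; y <- expr[ok]
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, sign = NA_character_,
                n = n, significant = FALSE))
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(rho = rho, p_value = p,
       sign = if (rho >= 0) "positive" else "negative",
       n = n, significant = p <= alpha)
}

#' Promoter-level methylation-expression correlation table
#'
#' @param prom_meth Output of [promoter_mean_methylation()].
#' @param expr Genes x samples FPKM matrix.
#' @param alpha Significance threshold (default 0.01).
#' @return `data.frame`: `gene_id`, `rho`, `p_value`, `sign`, `n`,
#'   `significant`. Genes absent from the expression table are skipped.
#' @export
correlate_promoters_expression <- function(prom_meth, expr, alpha = 0.01) {
  genes <- intersect(rownames(prom_meth$meth), rownames(expr))
  shared <- intersect(colnames(prom_meth$meth), colnames(expr))
  rows <- lapply(genes, function(g) {
    r <- tryCatch(
      spearman_methylation_expression(prom_meth$meth[g, shared],
                                      expr[g, shared], alpha),
      error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(gene_id = g, rho = r$rho, p_value = r$p_value,
               sign = if (is.na(r$rho)) NA_character_ else r$sign,
               n = r$n, significant = r$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), rho = numeric(),
                      p_value = numeric(), sign = character(),
                      n = integer(), significant = logical())
  out
}

#' Assign sites to genes for site-level expression correlation
#'
#' Precedence: promoter owner > host gene (site inside the gene span) >
#' unassigned.
#'
#' @param sites Site `data.frame`.
#' @param genes Gene model list.
#' @param promoters Promoter `RegionSet` (computed from `genes` if `NULL`).
#' @return Character vector of gene ids (`NA` when unassigned).
#' @export
assign_site_genes <- function(sites, genes, promoters = NULL) {
  if (is.null(promoters)) promoters <- promoter_windows(genes)
  n <- nrow(sites)
  out <- rep(NA_character_, n)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L,
                                                     width = 1L))
  span_gr <- GenomicRanges::GRanges(
    vapply(genes, function(g) g$chrom, ""),
    IRanges::IRanges(vapply(genes, function(g) g$span[["start"]] + 1L,
                            integer(1)),
                     vapply(genes, function(g) g$span[["end"]],
                            integer(1))))
  span_ids <- vapply(genes, function(g) g$gene_id, "")
  ov <- GenomicRanges::findOverlaps(site_gr, span_gr, select = "first")
  out[!is.na(ov)] <- span_ids[ov[!is.na(ov)]]
  prom_gr <- .regions_to_granges(promoters)
  ovp <- GenomicRanges::findOverlaps(site_gr, prom_gr, select = "first")
  out[!is.na(ovp)] <- promoters$gene_id[ovp[!is.na(ovp)]]
  out
}

#' Site-level methylation-expression correlations
#'
#' Applies [spearman_methylation_expression()] per site against the
#' expression of its assigned gene; unassigned sites are skipped and
#' counted.
#'
#' @param mat A filtered `MethCountMatrix`.
#' @param gene_assignment Character vector from [assign_site_genes()].
#' @param expr Genes x samples FPKM matrix.
#' @param alpha Significance threshold.
#' @param min_pairs Minimum complete pairs per site (default 5).
#' @return `data.frame` per tested site with `rho`, `p_value`, `sign`,
#'   `n`, `significant`, `gene_id`; attribute `n_unassigned`.
#' @export
site_expression_correlation <- function(mat, gene_assignment, expr,
                                        alpha = 0.01, min_pairs = 5) {
  lv <- meth_levels(mat)
  shared <- intersect(mat$samples, colnames(expr))
  jj <- match(shared, mat$samples)
  assigned <- which(!is.na(gene_assignment) &
                      gene_assignment %in% rownames(expr))
  rows <- lapply(assigned, function(i) {
    g <- gene_assignment[i]
    m <- lv[i, jj]; e <- expr[g, shared]
    if (sum(!is.na(m) & !is.na(e)) < min_pairs) return(NULL)
    r <- spearman_methylation_expression(m, e, alpha)
    data.frame(mat$sites[i, , drop = FALSE], gene_id = g, rho = r$rho,
               p_value = r$p_value, sign = r$sign, n = r$n,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      rho = numeric(), p_value = numeric(),
                      sign = character(), n = integer(),
                      significant = logical())
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- nrow(mat$sites) - length(assigned)
  out
}

#' Rank-based two-group expression test
#'
#' Wilcoxon-Mann-Whitney rank-sum test (exact for small tie-free samples,
#' normal approximation with tie correction otherwise), two-sided. A
#' paired signed-rank variant is available for paired designs.
#'
#' @param values Numeric expression values.
#' @param groups Two-level grouping vector.
#' @param paired Use the paired signed-rank test (groups must then be
#'   aligned and of equal size).
#' @return List `statistic`, `p_value`. All-tied input returns `p = 1`.
#' @export
group_expression_test <- function(values, groups, paired = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  a <- values[groups == levels(groups)[1]]
  b <- values[groups == levels(groups)[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (length(unique(c(a, b))) == 1L)
    return(list(statistic = NA_real_, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = NULL))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Differential-expression tests for a gene set
#'
#' @param expr Genes x samples FPKM matrix.
#' @param groups Two-level grouping over the columns.
#' @param gene_ids Genes to test (default all rows).
#' @param alpha Significance threshold (default 0.01).
#' @return `data.frame` with `gene_id`, `statistic`, `p_value`,
#'   `significant`.
#' @export
expression_group_table <- function(expr, groups, gene_ids = rownames(expr),
                                   alpha = 0.01) {
  rows <- lapply(gene_ids, function(g) {
    r <- group_expression_test(expr[g, ], groups)
    data.frame(gene_id = g, statistic = r$statistic, p_value = r$p_value,
               significant = !is.na(r$p_value) & r$p_value <= alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
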