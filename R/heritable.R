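# Pedigree-shared (inheritable) methylation regions: pedigree-consistent
# DMC detection, window merging, expected CpG counts, and the genome-wide
# corrected binomial false-positive bound.

#' Parameters of the heritable-window statistic
#'
#' @param L Window length in bp (default 500).
#' @param min_N Minimum synclastic DMC count per window (default 5).
#' @param p Genome-wide DMC ratio in (0, 1); `NA` means estimate from the
#'   scan (fraction of tested sites called pedigree DMCs).
#' @param GS Genome size in bp; `NA` means take it from the genome object.
#' @param pfp_threshold Report windows with corrected false-positive
#'   probability at or below this (default 0.01).
#' @return `heritable_params` list.
#' @export
heritable_params <- function(L = 500, min_N = 5, p = NA, GS = NA,
                             pfp_threshold = 0.01) {
  stopifnot(L > 0, min_N >= 1)
  if (!is.na(p) && (p <= 0 || p >= 1)) stop("p must lie in (0, 1)")
  structure(list(L = L, min_N = min_N, p = p, GS = GS,
                 pfp_threshold = pfp_threshold),
            class = "heritable_params")
}

#' Expected CpG count of a window
#'
#' `ECG = (#C x #G) / L`: the number of CpG dinucleotides expected in an
#' L-bp sequence if its C and G bases were arranged at random. For a
#' uniformly random 500-bp sequence (125 C, 125 G) this is 31.25, i.e.
#' about 31.
#'
#' @param c_count,g_count Base counts (>= 0).
#' @param L Sequence length (> 0).
#' @return Numeric ECG.
#' @export
expected_cpg_count <- function(c_count, g_count, L) {
  if (any(L <= 0)) stop("L must be positive")
  if (any(c_count < 0) || any(g_count < 0)) stop("counts must be >= 0")
  c_count * g_count / L
}

#' Genome-wide corrected false-positive probability of a heritable window
#'
#' Under the null, the number of synclastic DMCs among the window's CpGs is
#' `X ~ Bin(round(ECG), p/2)` (`p` the genome-wide DMC ratio, halved
#' because the window's DMCs must share one of the two directions). The
#' Bonferroni-style bound over all `GS / L` windows of both directions is
#'
#' `P_fp(X >= N) = 2 (1 - P(X < N)) GS / L`,
#'
#' reported uncapped (it is a bound, not a probability).
#'
#' @param N Observed synclastic DMC count (integer >= 0).
#' @param ECG Expected CpG count; the binomial support uses `round(ECG)`.
#' @param p Genome-wide DMC ratio in (0, 1).
#' @param GS Genome size in bp.
#' @param L Window length in bp.
#' @return Numeric bound (0 when `N > round(ECG)`).
#' @examples
#' round(pfp(5, 31, 0.003, 2.5e9, 500), 3)  # 0.012
#' @export
pfp <- function(N, ECG, p, GS, L) {
  if (any(N < 0) || any(N != round(N))) stop("N must be a non-negative integer")
  if (any(p <= 0) || any(p / 2 >= 1)) stop("need 0 < p and p/2 < 1")
  if (any(L <= 0) || any(GS <= 0)) stop("GS and L must be positive")
  size <- round(ECG)
  tail <- ifelse(N > size, 0,
                 stats::pbinom(N - 1, size = size, prob = p / 2,
                               lower.tail = FALSE))
  2 * tail * GS / L
}

#' Pedigree-consistent DMC calls
#'
#' A site is a pedigree DMC between the two pedigrees of one tissue iff
#' (i) the pooled beta-posterior minimum-difference test passes
#' (`delta`, `alpha`), and (ii) the per-individual posterior mean levels
#' separate completely: every cross-pedigree pair of individuals differs in
#' the same direction.
#'
#' @param mat A filtered `MethCountMatrix`.
#' @param samples Sample sheet covering the matrix columns.
#' @param tissue Tissue to scan (sheet value); `NULL` uses all samples.
#' @param pedigrees Optional length-2 character vector naming the two
#'   pedigrees; defaults to the two pedigree ids present.
#' @param delta,alpha,grid_n Minimum-difference test parameters.
#' @param min_per_pedigree Minimum samples per pedigree (default 2).
#' @return `data.frame` of all tested sites: site columns, `p_small`,
#'   `level_diff`, `direction`, `consistent` (rule ii), `is_dmc`
#'   (both rules). Attribute `n_tested`.
#' @export
pedigree_dmc <- function(mat, samples, tissue = NULL, pedigrees = NULL,
                         delta = 0.3, alpha = 0.01, grid_n = 512,
                         min_per_pedigree = 2) {
  samples <- samples[match(mat$samples, samples$sample_id), ]
  keep <- if (is.null(tissue)) rep(TRUE, nrow(samples)) else
    samples$tissue == tissue
  if (!any(keep)) stop("no samples in tissue '", tissue, "'")
  mat <- subset_matrix(mat, samples = which(keep))
  samples <- samples[keep, ]
  peds <- if (is.null(pedigrees)) sort(unique(samples$pedigree_id)) else
    pedigrees
  if (length(peds) < 2)
    stop("need two pedigrees in the compared tissue; found ",
         length(peds))
  if (length(peds) > 2)
    stop("more than two pedigrees present; name two via 'pedigrees'")
  idx_a <- which(samples$pedigree_id == peds[1])
  idx_b <- which(samples$pedigree_id == peds[2])
  if (length(idx_a) < min_per_pedigree || length(idx_b) < min_per_pedigree)
    stop("each pedigree needs at least ", min_per_pedigree, " samples")
  res <- .mindiff_scan(mat, idx_a, idx_b, delta, alpha, grid_n)
  # rule (ii): complete separation of per-individual posterior means
  post <- beta_posterior(mat$meth, mat$total - mat$meth)$mean
  rng <- function(idx, fn) suppressWarnings(
    apply(post[, idx, drop = FALSE], 1, fn, na.rm = TRUE))
  mins_b <- rng(idx_b, min); maxs_b <- rng(idx_b, max)
  mins_a <- rng(idx_a, min); maxs_a <- rng(idx_a, max)
  consistent <- is.finite(mins_a) & is.finite(mins_b) &
    ((mins_b > maxs_a) | (maxs_b < mins_a))
  out <- data.frame(res, consistent = consistent,
                    stringsAsFactors = FALSE)
  out$is_dmc <- res$is_dmc & consistent
  attr(out, "n_tested") <- sum(!is.na(res$p_small))
  attr(out, "pedigrees") <- peds
  out
}

#' Scan for heritable methylation windows
#'
#' Merges pedigree DMCs into candidate regions (gap = `L`), keeps regions
#' with at least `min_N` synclastic DMCs, computes each region's ECG from
#' its actual C and G counts over a span of `max(L, region length)` bp
#' (centred on the region, clipped at chromosome edges), and reports the
#' regions whose corrected false-positive bound [pfp()] is at or below the
#' threshold.
#'
#' @param pdmc Output of [pedigree_dmc()].
#' @param genome `GenomeSequence` for local C/G counting and `GS`.
#' @param params [heritable_params()].
#' @return `data.frame` of reported windows: `chrom`, `start`, `end`, `N`
#'   (synclastic DMCs), `n_sites`, `ECG`, `p_fp`, `direction`. Attributes
#'   `p_used` and `candidates` (all regions passing `min_N`, before the
#'   `p_fp` cut).
#' @export
scan_heritable_windows <- function(pdmc, genome,
                                   params = heritable_params()) {
  n_tested <- attr(pdmc, "n_tested")
  dmcs <- pdmc[pdmc$is_dmc, , drop = FALSE]
  p_used <- params$p
  if (is.na(p_used)) {
    if (is.null(n_tested) || n_tested == 0 || nrow(dmcs) == 0)
      p_used <- NA_real_
    else p_used <- nrow(dmcs) / n_tested
  }
  GS <- if (is.na(params$GS)) genome$GS else params$GS
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), N = integer(), n_sites = integer(),
                      ECG = numeric(), p_fp = numeric(),
                      direction = character())
  if (nrow(dmcs) == 0 || is.na(p_used)) {
    attr(empty, "p_used") <- p_used
    attr(empty, "candidates") <- empty
    return(empty)
  }
  regions <- merge_dmrs(dmcs, gap = params$L)
  regions$N <- pmax(regions$n_up, regions$n_down)
  regions <- regions[regions$N >= params$min_N, , drop = FALSE]
  if (nrow(regions) == 0) {
    attr(empty, "p_used") <- p_used
    attr(empty, "candidates") <- empty
    return(empty)
  }
  ecg <- numeric(nrow(regions)); span_len <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    len <- regions$end[i] - regions$start[i]
    Lw <- max(params$L, len)
    pad <- Lw - len
    s <- regions$start[i] - floor(pad / 2)
    e <- regions$end[i] + ceiling(pad / 2)
    clen <- genome$lengths[[regions$chrom[i]]]
    if (s < 0) { e <- min(e - s, clen); s <- 0 }
    if (e > clen) { s <- max(0, s - (e - clen)); e <- clen }
    sub <- substr(chrom_seq(genome, regions$chrom[i]), s + 1L, e)
    bc <- .base_counts(sub)
    span_len[i] <- e - s
    ecg[i] <- expected_cpg_count(bc[["C"]], bc[["G"]], span_len[i])
  }
  p_fp <- vapply(seq_len(nrow(regions)), function(i)
    pfp(regions$N[i], ecg[i], p_used, GS, span_len[i]), numeric(1))
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, N = regions$N,
                    n_sites = regions$n_sites, ECG = ecg, p_fp = p_fp,
                    direction = ifelse(regions$n_up >= regions$n_down,
                                       "up", "down"),
                    stringsAsFactors = FALSE)
  keep <- out$p_fp <= params$pfp_threshold
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "p_used") <- p_used
  attr(res, "candidates") <- out
  res
}
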