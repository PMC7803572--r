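# CpG context: CpG-island detection by the length/GC/obs-exp criterion,
# island/shore/shelf bands, genic classification, and promoter windows.

.base_counts <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(C = sum(v == "C"), G = sum(v == "G"), N = sum(v == "N"),
    L = sum(v != "N"))
}

.count_cpg <- function(seq) {
  # overlap-free by construction (CG cannot overlap itself)
  length(gregexpr("CG", seq, fixed = TRUE)[[1]]) *
    (regexpr("CG", seq, fixed = TRUE) > 0)
}

#' CpG observed/expected ratio of a sequence
#'
#' `(#CpG dinucleotides x L) / (#C x #G)` with `L` the number of non-N
#' bases; returns 0 when the sequence contains no C or no G.
#'
#' @param seq Character scalar over A/C/G/T/N.
#' @return Numeric ratio.
#' @examples
#' obs_exp_ratio("CGCGCGCG") # 2
#' @export
obs_exp_ratio <- function(seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0)
    stop("seq must be a non-empty character scalar")
  if (nchar(seq) < 2) stop("sequence length must be >= 2")
  bc <- .base_counts(seq)
  if (bc["C"] == 0 || bc["G"] == 0) return(0)
  cpg <- .count_cpg(seq)
  unname(cpg * bc["L"] / (bc["C"] * bc["G"]))
}

#' GC fraction of a sequence (N bases excluded)
#' @param seq Character scalar.
#' @return Numeric in \[0,1\].
#' @export
gc_fraction <- function(seq) {
  bc <- .base_counts(seq)
  if (bc["L"] == 0) return(0)
  unname((bc["C"] + bc["G"]) / bc["L"])
}

#' Detect CpG islands by sliding-window union
#'
#' Slides a window along each chromosome, keeps windows with GC content
#' above `min_gc` and CpG observed/expected ratio above `min_oe`, unions the
#' qualifying windows, and re-verifies the three criteria (length strictly
#' greater than `min_len`, GC, obs/exp) on each merged interval. This is a
#' self-contained approximation of the classical island-annotation
#' procedure; an externally provided island BED can be used instead
#' anywhere a `RegionSet` of islands is accepted.
#'
#' @param genome A `GenomeSequence`.
#' @param min_len Minimum merged length, strict (default 200 bp).
#' @param min_gc Minimum GC fraction, strict (default 0.50).
#' @param min_oe Minimum observed/expected CpG ratio, strict (default 0.60).
#' @param window Sliding window size in bp (default 200).
#' @param step Window step in bp (default 1).
#' @return A [region_set()] labelled `"CGI"`.
#' @export
detect_cgis <- function(genome, min_len = 200, min_gc = 0.50, min_oe = 0.60,
                        window = 200, step = 1) {
  stopifnot(min_len > 0, window > 0, step > 0)
  out <- list()
  for (chrom in names(genome$seqs)) {
    L <- genome$lengths[[chrom]]
    if (window > L) {
      message("detect_cgis: chromosome ", chrom,
              " shorter than window; skipped")
      next
    }
    seq <- chrom_seq(genome, chrom)
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    isC <- v == "C"; isG <- v == "G"; isN <- v == "N"
    isCpG <- c(isC[-L] & isG[-1], FALSE)
    cC <- cumsum(isC); cG <- cumsum(isG); cN <- cumsum(isN)
    cCpG <- cumsum(isCpG)
    starts <- seq.int(1L, L - window + 1L, by = step)
    ends <- starts + window - 1L
    wsum <- function(cs) cs[ends] - c(0, cs)[starts]
    nC <- wsum(cC); nG <- wsum(cG); nN <- wsum(cN)
    # CpG dinucleotides fully inside the window
    nCpG <- (cCpG[ends - 1L] - c(0, cCpG)[starts])
    eff <- window - nN
    gc_ok <- eff > 0 & (nC + nG) / eff > min_gc
    oe <- ifelse(nC * nG > 0, nCpG * eff / (nC * nG), 0)
    ok <- gc_ok & oe > min_oe
    if (!any(ok)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = starts[ok],
                                           end = ends[ok]))
    merged_start <- BiocGenerics::start(ir) - 1L  # to 0-based
    merged_end <- BiocGenerics::end(ir)
    keep <- logical(length(ir))
    for (i in seq_along(ir)) {
      sub <- substr(seq, merged_start[i] + 1L, merged_end[i])
      keep[i] <- (merged_end[i] - merged_start[i]) > min_len &&
        gc_fraction(sub) > min_gc && obs_exp_ratio(sub) > min_oe
    }
    if (any(keep))
      out[[chrom]] <- region_set(chrom, merged_start[keep],
                                 merged_end[keep], "CGI")
  }
  if (!length(out)) return(region_set())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("RegionSet", "data.frame")
  res
}

#' Classify sites relative to CpG islands
#'
#' A site inside an island is `CGI`; otherwise its integer distance `d` from
#' the nearest island edge (adjacent base has `d = 1`) places it in the
#' `shore` band (`1 <= d < shore_bp`), the `shelf` band
#' (`shore_bp <= d < shore_bp + shelf_bp`), or `open_sea`. The nearest
#' island decides ties.
#'
#' @param sites `data.frame` with `chrom` and `pos` columns.
#' @param cgis `RegionSet` of merged, non-overlapping islands.
#' @param shore_bp Shore band width (default 2000).
#' @param shelf_bp Shelf band width beyond the shore (default 2000).
#' @return Factor vector (`CGI`, `shore`, `shelf`, `open_sea`) per site.
#' @export
classify_island_context <- function(sites, cgis, shore_bp = 2000,
                                    shelf_bp = 2000) {
  n <- nrow(sites)
  d <- rep(Inf, n)
  if (nrow(cgis)) {
    for (chrom in unique(sites$chrom)) {
      si <- which(sites$chrom == chrom)
      ci <- cgis[cgis$chrom == chrom, , drop = FALSE]
      if (!nrow(ci)) next
      pos <- sites$pos[si]
      dd <- rep(Inf, length(si))
      for (k in seq_len(nrow(ci))) {
        inside <- pos >= ci$start[k] & pos < ci$end[k]
        left <- pmax(ci$start[k] - pos, 0)
        right <- pmax(pos - (ci$end[k] - 1L), 0)
        dk <- ifelse(inside, 0, pmax(left, right))
        dd <- pmin(dd, dk)
      }
      d[si] <- dd
    }
  }
  cls <- ifelse(d == 0, "CGI",
         ifelse(d < shore_bp, "shore",
         ifelse(d < shore_bp + shelf_bp, "shelf", "open_sea")))
  factor(cls, levels = c("CGI", "shore", "shelf", "open_sea"))
}

#' Classify sites by genic context
#'
#' Precedence `five_prime_UTR > exon > intron > intergenic` across all
#' overlapping genes; `intron` means inside a gene span but in no exon.
#'
#' @param sites `data.frame` with `chrom` and `pos`.
#' @param genes List of [gene_model()] objects.
#' @return Factor per site.
#' @export
classify_genic_context <- function(sites, genes) {
  n <- nrow(sites)
  in_utr <- logical(n); in_exon <- logical(n); in_span <- logical(n)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos + 1L,
                                                     width = 1L))
  collect <- function(getter) {
    rows <- do.call(rbind, lapply(genes, getter))
    if (is.null(rows) || nrow(rows) == 0) return(NULL)
    GenomicRanges::GRanges(rows$chrom,
                           IRanges::IRanges(rows$start + 1L, rows$end))
  }
  utr_gr <- collect(function(g) if (nrow(g$utr5))
    data.frame(chrom = g$chrom, start = g$utr5[, 1], end = g$utr5[, 2]))
  exon_gr <- collect(function(g)
    data.frame(chrom = g$chrom, start = g$exons[, 1], end = g$exons[, 2]))
  span_gr <- collect(function(g)
    data.frame(chrom = g$chrom, start = g$span[["start"]],
               end = g$span[["end"]]))
  hit <- function(gr) if (is.null(gr)) logical(n) else
    IRanges::overlapsAny(site_gr, gr)
  in_utr <- hit(utr_gr); in_exon <- hit(exon_gr); in_span <- hit(span_gr)
  cls <- ifelse(in_utr, "five_prime_UTR",
         ifelse(in_exon, "exon",
         ifelse(in_span, "intron", "intergenic")))
  factor(cls, levels = c("five_prime_UTR", "exon", "intron", "intergenic"))
}

#' Promoter window of a gene
#'
#' The expression-correlation promoter: `up` bp upstream of the TSS to
#' `down` bp downstream, in genomic order, clipped at chromosome bounds.
#' For a plus-strand TSS `t` this is `[t - up, t + down)`; for a
#' minus-strand TSS, `[t - down + 1, t + up + 1)`.
#'
#' @param gene A [gene_model()].
#' @param up Upstream extent in bp (default 800).
#' @param down Downstream extent in bp (default 200).
#' @param genome Optional `GenomeSequence` for upper clipping.
#' @return One-row [region_set()] labelled `promoter:<gene_id>`.
#' @export
promoter_window <- function(gene, up = 800, down = 200, genome = NULL) {
  t <- gene$tss
  if (gene$strand == "+") {
    s <- t - up; e <- t + down
  } else {
    s <- t - down + 1L; e <- t + up + 1L
  }
  s <- max(s, 0L)
  if (!is.null(genome)) e <- min(e, genome$lengths[[gene$chrom]])
  region_set(gene$chrom, s, e, paste0("promoter:", gene$gene_id))
}

#' Promoter windows for a gene list
#' @param genes List of gene models.
#' @inheritParams promoter_window
#' @return `RegionSet` with one row per gene and a `gene_id` column.
#' @export
promoter_windows <- function(genes, up = 800, down = 200, genome = NULL) {
  rows <- lapply(genes, promoter_window, up = up, down = down,
                 genome = genome)
  out <- do.call(rbind, rows)
  out$gene_id <- vapply(genes, function(g) g$gene_id, "")
  rownames(out) <- NULL
  class(out) <- c("RegionSet", "data.frame")
  out
}

#' Promoter-DMR screening regions (1 kb upstream plus first exon)
#'
#' The region used when screening DMRs near genes: TSS to 1 kb upstream
#' together with the first exon span. This is deliberately distinct from
#' the -800/+200 promoter used for expression correlation.
#'
#' @param genes List of gene models.
#' @param upstream Upstream extent (default 1000 bp).
#' @return `RegionSet` with a `gene_id` column.
#' @export
dmr_screen_regions <- function(genes, upstream = 1000) {
  rows <- lapply(genes, function(g) {
    if (g$strand == "+") {
      first_exon <- g$exons[1, ]
      s <- max(g$tss - upstream, 0L)
      region_set(g$chrom, c(s, first_exon[1]),
                 c(max(g$tss, s + 1L), first_exon[2]),
                 paste0("screen:", g$gene_id))
    } else {
      first_exon <- g$exons[nrow(g$exons), ]
      region_set(g$chrom, c(g$tss + 1L, first_exon[1]),
                 c(g$tss + 1L + upstream, first_exon[2]),
                 paste0("screen:", g$gene_id))
    }
  })
  out <- do.call(rbind, Map(function(r, g) {
    r$gene_id <- g$gene_id; r
  }, rows, genes))
  rownames(out) <- NULL
  class(out) <- c("RegionSet", "data.frame")
  out
}

#' Enumerate CpG sites of a genome
#'
#' Scans each chromosome for CG dinucleotides. With both strands requested
#' (the default accounting), each occurrence at position p yields a
#' plus-strand site at p and a minus-strand site at p+1, as distinct
#' records.
#'
#' @param genome A `GenomeSequence`.
#' @param strands `"both"` or `"plus"`.
#' @return `data.frame` with `chrom`, `pos`, `strand`, sorted.
#' @export
cpg_sites_from_genome <- function(genome, strands = c("both", "plus")) {
  strands <- match.arg(strands)
  rows <- lapply(names(genome$seqs), function(chrom) {
    seq <- chrom_seq(genome, chrom)
    hits <- gregexpr("CG", seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    p <- as.integer(hits) - 1L  # 0-based C position on plus strand
    if (strands == "both") {
      data.frame(chrom = chrom, pos = c(p, p + 1L),
                 strand = rep(c("+", "-"), each = length(p)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = chrom, pos = p, strand = "+",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  out <- out[order(out$chrom, out$pos, out$strand, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Full per-site context table
#'
#' @param sites Site `data.frame` (`chrom`, `pos`, `strand`).
#' @param cgis Island `RegionSet`.
#' @param genes Gene model list.
#' @param promoters Optional promoter `RegionSet` from [promoter_windows()];
#'   computed from `genes` when `NULL`.
#' @param shore_bp,shelf_bp Band widths.
#' @return `data.frame` with `island_class`, `genic_class`, `in_promoter_of`
#'   (comma-separated gene ids, empty when none) and the derived
#'   `utr5_cgi` flag (site in both a 5'UTR and an island).
#' @export
cpg_context <- function(sites, cgis, genes, promoters = NULL,
                        shore_bp = 2000, shelf_bp = 2000) {
  island <- classify_island_context(sites, cgis, shore_bp, shelf_bp)
  genic <- classify_genic_context(sites, genes)
  if (is.null(promoters)) promoters <- promoter_windows(genes)
  prom <- character(nrow(sites))
  if (nrow(promoters)) {
    site_gr <- GenomicRanges::GRanges(sites$chrom,
                                      IRanges::IRanges(sites$pos + 1L,
                                                       width = 1L))
    prom_gr <- .regions_to_granges(promoters)
    ov <- GenomicRanges::findOverlaps(site_gr, prom_gr)
    if (length(ov)) {
      by_site <- split(promoters$gene_id[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov))
      prom[as.integer(names(by_site))] <-
        vapply(by_site, paste, "", collapse = ",")
    }
  }
  data.frame(sites, island_class = island, genic_class = genic,
             in_promoter_of = prom,
             utr5_cgi = island == "CGI" & genic == "five_prime_UTR",
             stringsAsFactors = FALSE)
}
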