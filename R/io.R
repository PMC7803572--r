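# Shared data model and readers/writers for the standard formats the
# pipeline touches. All internal coordinates are 0-based half-open; the GTF
# reader converts from 1-based inclusive at the boundary.

#' Genome sequence container
#'
#' Wraps a named `DNAStringSet` together with per-chromosome lengths and the
#' total genome size `GS` (the quantity entering the genome-wide corrected
#' false-positive bound of [pfp()]).
#'
#' @param seqs Named character vector or `DNAStringSet` of chromosome
#'   sequences over the alphabet A/C/G/T/N.
#' @return An object of class `GenomeSequence`: a list with elements `seqs`
#'   (`DNAStringSet`), `lengths` (named integer) and `GS` (total size in bp).
#' @examples
#' g <- genome_sequence(c(c1 = "ACGTACGT"))
#' g$GS
#' @export
genome_sequence <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicated chromosome names")
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  structure(list(seqs = seqs, lengths = lens, GS = sum(as.numeric(lens))),
            class = "GenomeSequence")
}

#' @export
print.GenomeSequence <- function(x, ...) {
  cat("GenomeSequence:", length(x$seqs), "chromosome(s), GS =", x$GS, "bp\n")
  invisible(x)
}

#' Read a genome FASTA file
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A [genome_sequence()] object.
#' @export
read_fasta <- function(path) {
  genome_sequence(Biostrings::readDNAStringSet(path))
}

#' Write a genome to FASTA
#'
#' @param genome A `GenomeSequence`.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$seqs, path)
  invisible(path)
}

#' Extract one chromosome as a plain character string
#' @param genome A `GenomeSequence`.
#' @param chrom Chromosome name.
#' @return Character scalar.
#' @export
chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome$seqs)) stop("unknown chromosome: ", chrom)
  as.character(genome$seqs[[chrom]])
}

#' Methylation count matrix
#'
#' The pipeline's central object: per-CpG methylated and total read counts
#' across samples. Sites on the two strands are distinct records. Cells that
#' were not observed in a sample (absent from its file, or observed with
#' total coverage 0) are missing (`NA`), never zero.
#'
#' @param sites `data.frame` with columns `chrom`, `pos` (0-based position of
#'   the cytosine), `strand` (`"+"` or `"-"`).
#' @param samples Character vector of sample ids (column order).
#' @param meth,total Integer matrices, sites x samples; `NA` marks missing
#'   cells and must match between the two matrices.
#' @return An object of class `MethCountMatrix`.
#' @export
meth_count_matrix <- function(sites, samples, meth, total) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "strand") %in% names(sites)))
  if (any(sites$pos < 0)) stop("site positions must be >= 0")
  if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, strand) site records")
  meth <- as.matrix(meth); total <- as.matrix(total)
  storage.mode(meth) <- "integer"; storage.mode(total) <- "integer"
  if (!identical(dim(meth), dim(total)) ||
      nrow(meth) != nrow(sites) || ncol(meth) != length(samples))
    stop("count matrix dimensions do not match sites/samples")
  if (!identical(unname(is.na(meth)), unname(is.na(total))))
    stop("missing mask must agree between meth and total")
  # a covered cell with zero total carries no level information: mark missing
  zero <- !is.na(total) & total == 0L
  meth[zero] <- NA_integer_; total[zero] <- NA_integer_
  ok <- !is.na(total)
  if (any(meth[ok] < 0L) || any(total[ok] < 0L)) stop("negative counts")
  if (any(meth[ok] > total[ok])) stop("meth count exceeds total count")
  ord <- order(sites$chrom, sites$pos, sites$strand, method = "radix")
  sites <- sites[ord, c("chrom", "pos", "strand"), drop = FALSE]
  rownames(sites) <- NULL
  meth <- meth[ord, , drop = FALSE]; total <- total[ord, , drop = FALSE]
  dimnames(meth) <- dimnames(total) <- list(NULL, samples)
  structure(list(sites = sites, samples = as.character(samples),
                 meth = meth, total = total),
            class = "MethCountMatrix")
}

#' @export
print.MethCountMatrix <- function(x, ...) {
  cat("MethCountMatrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples;", sum(is.na(x$total)), "missing cells\n")
  invisible(x)
}

#' Number of sites in a MethCountMatrix
#' @param mat A `MethCountMatrix`.
#' @return Integer site count.
#' @export
n_sites <- function(mat) nrow(mat$sites)

#' Subset a MethCountMatrix
#'
#' @param mat A `MethCountMatrix`.
#' @param sites Integer/logical index over rows (sites); `NULL` keeps all.
#' @param samples Character vector of sample ids or index; `NULL` keeps all.
#' @return A `MethCountMatrix`.
#' @export
subset_matrix <- function(mat, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_len(nrow(mat$sites)) else sites
  sj <- if (is.null(samples)) seq_along(mat$samples) else {
    if (is.character(samples)) match(samples, mat$samples) else samples
  }
  if (anyNA(sj)) stop("unknown sample id(s)")
  meth_count_matrix(mat$sites[si, , drop = FALSE], mat$samples[sj],
                    mat$meth[si, sj, drop = FALSE],
                    mat$total[si, sj, drop = FALSE])
}

#' Read a MethylDackel-style bedGraph of CpG counts
#'
#' Consumes the tab-separated dialect written by methylation extractors:
#' `chrom  start  end  methylation_percent  n_methylated  n_unmethylated`,
#' with an optional leading `track` line. The CpG-report dialect carries no
#' per-row strand; the strand of every site is set by the `strand` argument
#' (load plus- and minus-strand extracts separately to keep both strands as
#' distinct records).
#'
#' @param path Path to the bedGraph file.
#' @param sample_id Sample identifier attached to the records.
#' @param strand Strand assigned to all rows (default `"+"`).
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `meth`,
#'   `total`, `sample_id`, sorted by (chrom, pos). Rows with zero total
#'   coverage are retained with `NA` counts (missing).
#' @export
read_methyldackel_bedgraph <- function(path, sample_id, strand = "+") {
  lines <- readLines(path)
  skip <- length(lines) > 0 && startsWith(lines[1], "track")
  first <- if (skip) 2L else 1L
  if (first > length(lines))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      total = integer(), sample_id = character()))
  body <- lines[first:length(lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6)) {
    bad <- which(nf < 6)[1]
    stop("malformed bedGraph row at line ", bad + first - 1L, " of ", path,
         ": expected 6 tab-separated fields")
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  m <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 5L)))
  u <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 6L)))
  if (anyNA(start) || anyNA(m) || anyNA(u)) {
    bad <- which(is.na(start) | is.na(m) | is.na(u))[1]
    stop("non-numeric field in bedGraph row at line ", bad + first - 1L,
         " of ", path)
  }
  if (any(m < 0L) || any(u < 0L)) stop("negative counts in ", path)
  total <- m + u
  miss <- total == 0L
  m[miss] <- NA_integer_; total[miss] <- NA_integer_
  out <- data.frame(chrom = chrom, pos = start, strand = strand,
                    meth = m, total = total, sample_id = sample_id,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, method = "radix"), , drop = FALSE]
}

#' Assemble per-sample count records into a MethCountMatrix
#'
#' Takes the union of sites across samples; cells absent in a sample are
#' marked missing, not zero.
#'
#' @param records Named list (by sample id) of data.frames as returned by
#'   [read_methyldackel_bedgraph()], or one data.frame with a `sample_id`
#'   column.
#' @param sample_sheet Optional sample sheet; every sheet sample must be
#'   present among the records and the matrix columns follow sheet order.
#' @return A [meth_count_matrix()].
#' @export
assemble_matrix <- function(records, sample_sheet = NULL) {
  if (is.data.frame(records)) records <- split(records, records$sample_id)
  if (length(records) < 1) stop("need records for at least one sample")
  ids <- names(records)
  if (!is.null(sample_sheet)) {
    missing <- setdiff(sample_sheet$sample_id, ids)
    if (length(missing))
      stop("sample(s) in sheet without count records: ",
           paste(missing, collapse = ", "))
    ids <- sample_sheet$sample_id
    records <- records[ids]
  }
  keys <- lapply(records, function(r) paste(r$chrom, r$pos, r$strand))
  for (i in seq_along(records)) {
    if (anyDuplicated(keys[[i]]))
      stop("duplicate site records within sample ", ids[i])
  }
  all_keys <- unique(unlist(keys, use.names = FALSE))
  first <- do.call(rbind, lapply(records, function(r)
    r[, c("chrom", "pos", "strand")]))
  sites <- first[match(all_keys, paste(first$chrom, first$pos, first$strand)), ]
  rownames(sites) <- NULL
  n <- length(all_keys)
  meth <- matrix(NA_integer_, n, length(ids))
  total <- matrix(NA_integer_, n, length(ids))
  for (i in seq_along(records)) {
    idx <- match(keys[[i]], all_keys)
    meth[idx, i] <- records[[i]]$meth
    total[idx, i] <- records[[i]]$total
  }
  meth_count_matrix(sites, ids, meth, total)
}

#' Merge symmetric CpG strand pairs by summing counts
#'
#' Collapses a plus-strand site at position p and the minus-strand site at
#' p+1 into a single plus-strand record with summed counts. Default pipeline
#' behaviour keeps both strands as distinct sites; this is an opt-in
#' alternative accounting.
#'
#' @param mat A `MethCountMatrix`.
#' @return A `MethCountMatrix` with merged pairs.
#' @export
merge_symmetric_cpgs <- function(mat) {
  s <- mat$sites
  plus <- which(s$strand == "+")
  minus_key <- paste(s$chrom, s$pos - 1L)[s$strand == "-"]
  minus_idx <- which(s$strand == "-")
  mate <- match(paste(s$chrom[plus], s$pos[plus]), minus_key)
  meth <- mat$meth[plus, , drop = FALSE]
  total <- mat$total[plus, , drop = FALSE]
  has_mate <- !is.na(mate)
  mi <- minus_idx[mate[has_mate]]
  add <- function(a, b) ifelse(is.na(a) & is.na(b), NA_integer_,
                               ifelse(is.na(a), b, ifelse(is.na(b), a, a + b)))
  meth[has_mate, ] <- add(meth[has_mate, , drop = FALSE],
                          mat$meth[mi, , drop = FALSE])
  total[has_mate, ] <- add(total[has_mate, , drop = FALSE],
                           mat$total[mi, , drop = FALSE])
  orphan_minus <- setdiff(minus_idx, mi)
  sites <- rbind(s[plus, ], s[orphan_minus, ])
  meth <- rbind(meth, mat$meth[orphan_minus, , drop = FALSE])
  total <- rbind(total, mat$total[orphan_minus, , drop = FALSE])
  meth_count_matrix(sites, mat$samples, meth, total)
}

#' Region set constructor
#'
#' Genomic intervals with a role label, 0-based half-open.
#'
#' @param chrom,start,end,label Vectors of equal length (label recycled).
#' @return `data.frame` with class `RegionSet`.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), label = character()) {
  if (length(start) && any(start >= end)) stop("regions require start < end")
  out <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                    end = as.integer(end),
                    label = rep_len(as.character(label), length(chrom)),
                    stringsAsFactors = FALSE)
  class(out) <- c("RegionSet", "data.frame")
  out
}

.regions_to_granges <- function(r) {
  GenomicRanges::GRanges(r$chrom,
                         IRanges::IRanges(start = r$start + 1L, end = r$end))
}

#' Read a BED file into a RegionSet
#'
#' @param path BED3/BED4 path.
#' @param genome Optional `GenomeSequence`; rows on unknown chromosomes are
#'   skipped with a warning stating the count.
#' @param label Label used when the file has no name column.
#' @return A [region_set()].
#' @export
read_bed <- function(path, genome = NULL, label = "region") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "label",
                                        "V5", "V6")[1:min(6, max(utils::count.fields(path, sep = "\t")))],
                          fill = TRUE)
  if (!"label" %in% names(df)) df$label <- label
  if (!is.null(genome)) {
    bad <- !(df$chrom %in% names(genome$lengths))
    if (any(bad)) {
      warning(sum(bad), " BED row(s) on unknown chromosome(s) skipped")
      df <- df[!bad, , drop = FALSE]
    }
  }
  region_set(df$chrom, df$start, df$end, df$label)
}

#' Write a RegionSet as BED4
#'
#' Coordinates are written exactly as stored (0-based half-open), so
#' write-then-read round-trips bit-exactly.
#'
#' @param regions A `RegionSet`.
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a minimal GTF into gene models
#'
#' Parses only `gene`, `exon` and `five_prime_utr` features and the `gene_id`
#' attribute. 1-based inclusive GTF coordinates are converted to 0-based
#' half-open. The TSS is the strand-appropriate extreme exon boundary.
#'
#' @param path GTF path.
#' @return List of gene models; each a list with `gene_id`, `chrom`,
#'   `strand`, `tss` (0-based), `exons` and `utr5` (2-column matrices of
#'   0-based half-open intervals) and `span` (gene extent).
#' @export
read_gtf_minimal <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- gr$type %in% c("gene", "exon", "five_prime_utr")
  gr <- gr[keep]
  ids <- unique(gr$gene_id)
  lapply(ids, function(id) {
    g <- gr[gr$gene_id == id]
    ex <- g[g$type == "exon"]
    ut <- g[g$type == "five_prime_utr"]
    if (length(ex) == 0) stop("gene ", id, " has no exon features")
    strand <- as.character(S4Vectors::runValue(BiocGenerics::strand(ex)))[1]
    exs <- cbind(start = BiocGenerics::start(ex) - 1L,
                 end = BiocGenerics::end(ex))
    exs <- exs[order(exs[, 1]), , drop = FALSE]
    uts <- if (length(ut)) cbind(start = BiocGenerics::start(ut) - 1L,
                                 end = BiocGenerics::end(ut))
           else matrix(integer(), 0, 2,
                       dimnames = list(NULL, c("start", "end")))
    tss <- if (strand == "-") max(exs[, 2]) - 1L else min(exs[, 1])
    gene_model(id, as.character(GenomeInfoDb::seqnames(ex))[1], strand,
               tss, exs, uts)
  })
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome.
#' @param strand `"+"` or `"-"`.
#' @param tss 0-based TSS position; must equal the strand-appropriate
#'   extreme exon boundary.
#' @param exons,utr5 2-column matrices (`start`, `end`), 0-based half-open;
#'   exons must be non-overlapping, 5'UTR intervals must lie inside exons.
#' @return List with class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, exons,
                       utr5 = matrix(integer(), 0, 2)) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("overlapping exons in gene ", gene_id)
  expected_tss <- if (strand == "-") max(exons[, 2]) - 1L else min(exons[, 1])
  if (tss != expected_tss)
    stop("TSS of ", gene_id, " does not match exon boundary")
  utr5 <- matrix(as.integer(utr5), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  if (nrow(utr5)) {
    inside <- vapply(seq_len(nrow(utr5)), function(i)
      any(utr5[i, 1] >= exons[, 1] & utr5[i, 2] <= exons[, 2]), logical(1))
    if (!all(inside)) stop("5'UTR outside exon union in gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss = as.integer(tss), exons = exons, utr5 = utr5,
                 span = c(start = min(exons[, 1]), end = max(exons[, 2]))),
            class = "gene_model")
}

#' Write gene models as a minimal GTF
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gtf_minimal <- function(genes, path) {
  rows <- unlist(lapply(genes, function(g) {
    attr <- sprintf('gene_id "%s";', g$gene_id)
    line <- function(type, s, e)
      paste(g$chrom, "methkin", type, s + 1L, e, ".", g$strand, ".", attr,
            sep = "\t")
    c(line("gene", g$span["start"], g$span["end"]),
      vapply(seq_len(nrow(g$exons)), function(i)
        line("exon", g$exons[i, 1], g$exons[i, 2]), ""),
      if (nrow(g$utr5)) vapply(seq_len(nrow(g$utr5)), function(i)
        line("five_prime_utr", g$utr5[i, 1], g$utr5[i, 2]), ""))
  }), use.names = FALSE)
  writeLines(rows, path)
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header; required columns `sample_id`, `individual_id`,
#' `tissue`, `breed`, `age_years`, `sex`, `pedigree_id`; optional `sire_id`,
#' `dam_id` (empty/`NA` for founders). Parent ids not listed as individuals
#' are treated as unobserved founders by [kinship_from_pedigree()].
#'
#' @param path TSV path.
#' @return `data.frame` of sample records.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data.frame
#' @param df Sample sheet.
#' @return The validated data.frame (invisibly modified: NA-normalised
#'   parent ids).
#' @export
validate_sample_sheet <- function(df) {
  req <- c("sample_id", "individual_id", "tissue", "breed", "age_years",
           "sex", "pedigree_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids")
  if (any(!is.finite(df$age_years)) || any(df$age_years <= 0))
    stop("age_years must be positive")
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  for (col in c("sire_id", "dam_id")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
    df[[col]][df[[col]] %in% c("", ".", "NA")] <- NA_character_
  }
  df
}

#' Write a sample sheet
#' @param sheet Sample-sheet data.frame.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene x sample FPKM expression table
#'
#' First column `gene_id`, remaining columns one per sample, tab-separated.
#'
#' @param path TSV path.
#' @param sample_sheet Optional sheet; column ids are checked against it.
#' @return Numeric matrix, genes x samples, rownames = gene ids.
#' @export
read_expression <- function(path, sample_sheet = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(m < 0)) stop("FPKM values must be >= 0")
  if (!is.null(sample_sheet)) {
    unknown <- setdiff(colnames(m), sample_sheet$sample_id)
    if (length(unknown)) stop("expression columns not in sample sheet: ",
                              paste(unknown, collapse = ", "))
  }
  m
}

#' Write an expression matrix as TSV
#' @param expr Genes x samples matrix with rownames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a results table as TSV
#' @param table A data.frame.
#' @param path Output path.
#' @export
write_results_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize a MethCountMatrix to TSV
#'
#' One row per site: `chrom`, `pos`, `strand`, then per sample two columns
#' `<id>.meth` and `<id>.total`; missing cells are written as `NA`.
#' Write-then-read is the identity on counts, sites and missing mask.
#'
#' @param mat A `MethCountMatrix`.
#' @param path Output path.
#' @export
write_meth_matrix <- function(mat, path) {
  df <- mat$sites
  for (j in seq_along(mat$samples)) {
    df[[paste0(mat$samples[j], ".meth")]] <- mat$meth[, j]
    df[[paste0(mat$samples[j], ".total")]] <- mat$total[, j]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a MethCountMatrix written by [write_meth_matrix()]
#' @param path TSV path.
#' @return A `MethCountMatrix`.
#' @export
read_meth_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meth_cols <- grep("\\.meth$", names(df), value = TRUE)
  ids <- sub("\\.meth$", "", meth_cols)
  meth <- as.matrix(df[, paste0(ids, ".meth"), drop = FALSE])
  total <- as.matrix(df[, paste0(ids, ".total"), drop = FALSE])
  meth_count_matrix(df[, c("chrom", "pos", "strand")], ids, meth, total)
}

#' Write one sample of a MethCountMatrix as MethylDackel-style bedGraph
#' @param mat A `MethCountMatrix`.
#' @param sample_id Sample to export.
#' @param path Output path.
#' @export
write_methyldackel_bedgraph <- function(mat, sample_id, path) {
  j <- match(sample_id, mat$samples)
  if (is.na(j)) stop("unknown sample: ", sample_id)
  keep <- !is.na(mat$total[, j])
  s <- mat$sites[keep, ]
  m <- mat$meth[keep, j]; t <- mat$total[keep, j]
  lines <- c(sprintf("track type=\"bedGraph\" description=\"%s CpG\"",
                     sample_id),
             paste(s$chrom, s$pos, s$pos + 1L,
                   round(100 * m / t), m, t - m, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
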