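# End-to-end orchestration: config-driven stages over simulated or user
# data, with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Paths plus every module threshold, all defaulting to the analysis
#' defaults used throughout the package (coverage 10-300 in half the
#' samples; minimum difference 0.3 at alpha 0.01; 500-bp DMR merging; 5
#' synclastic DMCs; 10 promoter CpGs; -800/+200 promoter; island criterion
#' 200 bp / 50 percent GC / 0.6 obs-exp; 2-kb shore and shelf bands).
#'
#' @param genome,counts_dir,annotation,sample_sheet,expression,cgi_bed
#'   Input paths (`cgi_bed` optional: islands are detected from sequence
#'   when `NULL`).
#' @param min_cov,max_cov,min_presence_fraction Filter policy.
#' @param delta,alpha Differential-methylation thresholds.
#' @param dmr_gap DMR merge distance (bp).
#' @param min_synclastic Promoter-DMR screening count.
#' @param min_promoter_cpgs Promoter CpG threshold for expression
#'   integration.
#' @param promoter_up,promoter_down Promoter window extents.
#' @param cgi_min_len,cgi_min_gc,cgi_min_oe Island criterion.
#' @param shore_bp,shelf_bp Island band widths.
#' @param heritable_tissue Tissue scanned for pedigree-shared windows.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return `run_config` list.
#' @export
run_config <- function(genome, counts_dir, annotation, sample_sheet,
                       expression = NULL, cgi_bed = NULL,
                       min_cov = 10, max_cov = 300,
                       min_presence_fraction = 0.5,
                       delta = 0.3, alpha = 0.01, dmr_gap = 500,
                       min_synclastic = 5, min_promoter_cpgs = 10,
                       promoter_up = 800, promoter_down = 200,
                       cgi_min_len = 200, cgi_min_gc = 0.5,
                       cgi_min_oe = 0.6, shore_bp = 2000, shelf_bp = 2000,
                       heritable_tissue = "testis", seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load inputs, annotate CpG context, filter by coverage, compute
#' global statistics, scan DMCs (tissue via the kinship GLMM; breed and
#' sex via the minimum-difference test; ages pairwise within tissue),
#' merge DMRs and screen promoters, scan pedigree-shared heritable
#' windows, and integrate promoter methylation with expression. Writes
#' TSV/BED outputs per stage plus a JSON run manifest with parameters,
#' seed and row counts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisible list of all stage results (also written to disk).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$genome, config$counts_dir, config$annotation,
              config$sample_sheet))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = config[!(names(config) %in%
                     c("genome", "counts_dir", "annotation", "sample_sheet",
                       "expression", "cgi_bed"))],
                   inputs = config[c("genome", "counts_dir", "annotation",
                                     "sample_sheet", "expression",
                                     "cgi_bed")],
                   seed = config$seed, stages = list())
  note <- function(stage, n_rows) {
    manifest$stages[[stage]] <<- list(rows = n_rows)
  }

  genome <- read_fasta(config$genome)
  samples <- read_sample_sheet(config$sample_sheet)
  genes <- read_gtf_minimal(config$annotation)
  files <- list.files(config$counts_dir, pattern = "\\.bedGraph$",
                      full.names = TRUE)
  ids <- sub("\\.bedGraph$", "", basename(files))
  records <- Map(read_methyldackel_bedgraph, files, ids)
  names(records) <- ids
  mat <- assemble_matrix(records, samples)
  note("load", n_sites(mat))

  cgis <- if (!is.null(config$cgi_bed))
    read_bed(config$cgi_bed, genome, label = "CGI")
  else detect_cgis(genome, config$cgi_min_len, config$cgi_min_gc,
                   config$cgi_min_oe)
  proms <- promoter_windows(genes, config$promoter_up,
                            config$promoter_down, genome)
  ctx <- cpg_context(mat$sites, cgis, genes, proms,
                     config$shore_bp, config$shelf_bp)
  write_regions_bed(cgis, file.path(out_dir, "cgis.bed"))
  write_results_tsv(ctx, file.path(out_dir, "site_context.tsv"))
  note("annotate", nrow(ctx))

  fmat <- apply_site_filter(mat, filter_policy(config$min_cov,
                                               config$max_cov,
                                               config$min_presence_fraction))
  write_meth_matrix(fmat, file.path(out_dir, "filtered_counts.tsv"))
  note("filter", n_sites(fmat))

  gs <- global_stats(fmat, groups = samples$tissue[match(fmat$samples,
                                                         samples$sample_id)])
  write_results_tsv(data.frame(sample_id = fmat$samples,
                               mean_level = gs$sample_mean_level,
                               mean_entropy = gs$sample_mean_entropy),
                    file.path(out_dir, "global_stats.tsv"))
  note("global_stats", length(fmat$samples))

  dmc_tissue <- dmc_scan(fmat, samples, "tissue", method = "pql",
                         alpha = config$alpha)
  dmc_breed <- dmc_scan(subset_one_tissue(fmat, samples, "muscle"),
                        samples, "breed", method = "mindiff",
                        alpha = config$alpha, delta = config$delta)
  dmc_sex <- dmc_scan(subset_one_tissue(fmat, samples, "muscle"),
                      samples, "sex", method = "mindiff",
                      alpha = config$alpha, delta = config$delta)
  age <- pairwise_age_scan(subset_breed(fmat, samples, "BMX"), samples,
                           delta = config$delta, alpha = config$alpha)
  for (nm in c("tissue", "breed", "sex")) {
    obj <- get(paste0("dmc_", nm))
    write_results_tsv(obj, file.path(out_dir, paste0("dmc_", nm, ".tsv")))
    note(paste0("dmc_", nm), nrow(obj))
  }
  note("dmc_age_pairs", length(age$results))

  dmrs <- merge_dmrs(dmc_tissue, gap = config$dmr_gap)
  screened <- screen_promoter_dmrs(dmrs, dmr_screen_regions(genes),
                                   config$min_synclastic)
  write_results_tsv(dmrs, file.path(out_dir, "dmrs_tissue.tsv"))
  write_results_tsv(screened, file.path(out_dir, "dmrs_promoter.tsv"))
  note("dmrs", nrow(dmrs)); note("dmrs_promoter", nrow(screened))

  heritable <- tryCatch({
    pd <- pedigree_dmc(fmat, samples, tissue = config$heritable_tissue,
                       pedigrees = c("ped1", "ped2"),
                       delta = config$delta, alpha = config$alpha)
    scan_heritable_windows(pd, genome, heritable_params())
  }, error = function(e) {
    message("heritable scan skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(heritable)) {
    write_results_tsv(heritable, file.path(out_dir,
                                           "heritable_windows.tsv"))
    if (nrow(heritable))
      write_regions_bed(region_set(heritable$chrom, heritable$start,
                                   heritable$end, "heritable"),
                        file.path(out_dir, "heritable_windows.bed"))
    note("heritable", nrow(heritable))
  }

  integration <- NULL
  if (!is.null(config$expression) && file.exists(config$expression %||% "")) {
    expr <- read_expression(config$expression, samples)
    pm <- promoter_mean_methylation(fmat, proms, config$min_promoter_cpgs)
    integration <- correlate_promoters_expression(pm, expr, config$alpha)
    write_results_tsv(integration,
                      file.path(out_dir, "promoter_expression.tsv"))
    note("integrate", nrow(integration))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(matrix = fmat, context = ctx, cgis = cgis,
                 global = gs, dmc_tissue = dmc_tissue,
                 dmc_breed = dmc_breed, dmc_sex = dmc_sex, age = age,
                 dmrs = dmrs, dmrs_promoter = screened,
                 heritable = heritable, integration = integration,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subset a matrix to one tissue's samples
#' @param mat `MethCountMatrix`.
#' @param samples Sample sheet.
#' @param tissue Tissue value.
#' @return `MethCountMatrix`.
#' @export
subset_one_tissue <- function(mat, samples, tissue) {
  samples <- samples[match(mat$samples, samples$sample_id), ]
  subset_matrix(mat, samples = which(samples$tissue == tissue))
}

#' Subset a matrix to one breed's samples
#' @param mat `MethCountMatrix`.
#' @param samples Sample sheet.
#' @param breed Breed value.
#' @return `MethCountMatrix`.
#' @export
subset_breed <- function(mat, samples, breed) {
  samples <- samples[match(mat$samples, samples$sample_id), ]
  subset_matrix(mat, samples = which(samples$breed == breed))
}
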