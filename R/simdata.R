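# Synthetic genomes, pedigrees, WGBS count matrices and expression tables
# with the statistical structure the analysis assumes, plus ground-truth
# tables for every planted signal.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: 20 samples
#' (12 muscle + 8 testis) over two breeds, three adult age groups and two
#' pedigrees; a bimodal methylation landscape (CpG islands low, background
#' high, global mean near 70 percent); beta-binomial read counts; planted
#' tissue, age, breed and sex effects on the logit scale; pedigree-shared
#' windows; an individual genetic random effect with covariance
#' `sigma2 * K` from the pedigree; and expression coupled to promoter
#' methylation for a designated gene subset.
#'
#' @param seed Master seed; every generator derives its own stream from
#'   (seed, generator name), so adding a generator never perturbs others.
#' @param n_chroms,chrom_length Genome shape (default 2 x 100 kb).
#' @param gc_background Background GC fraction (default 0.38).
#' @param cgi_per_chrom,cgi_length,cgi_gc Planted island count, length and
#'   GC (defaults 4, 600 bp, 0.70; iid composition gives obs/exp near 1).
#' @param n_genes Number of genes (default 16).
#' @param tss_in_cgi_frac Fraction of genes whose TSS sits inside an
#'   island (default 0.5).
#' @param strands `"both"` (default) or `"plus"` CpG accounting.
#' @param mean_coverage,coverage_dispersion Negative-binomial coverage law
#'   (defaults 30x, size 8), truncated at 1.
#' @param cgi_low_mean,noncgi_high_mean,mu_sd Baseline level mixture:
#'   island-low and background-high means with logit-scale spread.
#' @param bb_concentration Beta-binomial concentration (default 20;
#'   `Inf` gives pure binomial counts).
#' @param n_tissue_dmc,tissue_delta Planted tissue-differential sites and
#'   logit effect size (defaults 300 sites, delta 2).
#' @param n_age_dmc,age_slope Planted age-dynamic sites and logit slope
#'   per year (defaults 150, 0.35).
#' @param n_breed_dmc,breed_delta Planted breed sites (defaults 150, 2).
#' @param n_sex_dmc,sex_delta Planted sex sites (defaults 50, 2).
#' @param n_pedigree_windows,pedigree_window_bp,pedigree_window_min_cpgs,pedigree_delta
#'   Pedigree-shared windows: count, width, minimum CpGs within the width,
#'   and the half-separation on the logit scale (each pedigree is shifted
#'   by +/- delta around logit 0).
#' @param sigma2 Genetic random-effect variance (default 0.5).
#' @param n_coupled_genes Genes whose expression tracks promoter
#'   methylation (default 6).
#' @param min_promoter_cpgs Minimum simulated promoter CpGs for a coupled
#'   gene (default 10).
#' @param promoter_variability Logit-scale SD of the per-sample promoter
#'   methylation shift given to coupled candidates (default 1.5).
#' @param coupling_intercept,coupling_slope log1p-FPKM intercept and
#'   absolute slope on promoter mean methylation (defaults 5, 4).
#' @param expression_noise_sd,uncoupled_sd Noise SDs for coupled and
#'   uncoupled genes (defaults 0.5, 1.5).
#' @return `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 2, chrom_length = 100000,
                       gc_background = 0.38,
                       cgi_per_chrom = 4, cgi_length = 600, cgi_gc = 0.70,
                       n_genes = 16, tss_in_cgi_frac = 0.5,
                       strands = "both",
                       mean_coverage = 30, coverage_dispersion = 8,
                       cgi_low_mean = 0.08, noncgi_high_mean = 0.80,
                       mu_sd = 0.8, bb_concentration = 20,
                       n_tissue_dmc = 300, tissue_delta = 2,
                       n_age_dmc = 150, age_slope = 0.35,
                       n_breed_dmc = 150, breed_delta = 2,
                       n_sex_dmc = 50, sex_delta = 2,
                       n_pedigree_windows = 2, pedigree_window_bp = 130,
                       pedigree_window_min_cpgs = 14, pedigree_delta = 2,
                       sigma2 = 0.5,
                       n_coupled_genes = 6, min_promoter_cpgs = 10,
                       promoter_variability = 1.5,
                       coupling_intercept = 5, coupling_slope = 4,
                       expression_noise_sd = 0.5, uncoupled_sd = 1.5) {
  cfg <- as.list(environment())
  probs <- c(cfg$gc_background, cfg$cgi_gc, cfg$cgi_low_mean,
             cfg$noncgi_high_mean, cfg$tss_in_cgi_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$sigma2 < 0) stop("sigma2 must be >= 0")
  if (cfg$chrom_length <= 10 * cfg$cgi_length)
    stop("chrom_length must exceed 10x cgi_length")
  deltas <- c(cfg$tissue_delta, cfg$age_slope, cfg$breed_delta,
              cfg$sex_delta, cfg$pedigree_delta)
  if (any(!is.finite(deltas))) stop("effect sizes must be finite")
  structure(cfg, class = "sim_config")
}

# Derive a generator-specific RNG seed from (master seed, stream name).
.stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((abs(seed) %% 20000L) * 100000L + h)
}

.with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(.stream_seed(seed, name))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

.sample_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a genome with planted CpG islands and gene models
#'
#' Background sequence is iid with the configured GC fraction (its 200-bp
#' windows fail the GC > 50 percent island criterion with overwhelming
#' probability); planted islands are iid at the island GC (observed/expected
#' CpG ratio near 1) and are re-drawn until they satisfy the detection
#' criterion, so every planted island is detectable in isolation. Genes are
#' laid out on a non-overlapping grid; a configurable fraction of TSSs fall
#' inside islands.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (`GenomeSequence`), `cgis` (`RegionSet` truth),
#'   `genes` (list of [gene_model()]).
#' @export
simulate_genome <- function(config = sim_config()) {
  .with_stream(config$seed, "genome", {
    slot <- 6000L
    n_slots <- config$chrom_length %/% slot
    genes_per_chrom <- ceiling(config$n_genes / config$n_chroms)
    n_cgi_genes <- round(config$n_genes * config$tss_in_cgi_frac)
    free_needed <- genes_per_chrom  # worst case all standalone
    if (config$cgi_per_chrom + free_needed > n_slots)
      stop("infeasible config: islands and genes overflow the chromosome")
    if (config$cgi_length > slot - 2500)
      stop("infeasible config: island longer than its slot")
    chroms <- character(config$n_chroms)
    names(chroms) <- paste0("chr", seq_len(config$n_chroms))
    cgi_rows <- list(); genes <- list()
    gene_i <- 0L
    for (ci in seq_len(config$n_chroms)) {
      chrom <- names(chroms)[ci]
      bases <- .sample_bases(config$chrom_length, config$gc_background)
      # islands occupy the first cgi_per_chrom slots
      for (k in seq_len(config$cgi_per_chrom)) {
        s0 <- (k - 1L) * slot
        start <- s0 + 2000L
        repeat {
          isl <- .sample_bases(config$cgi_length, config$cgi_gc)
          iseq <- paste(isl, collapse = "")
          if (gc_fraction(iseq) > 0.5 && obs_exp_ratio(iseq) > 0.6) break
        }
        bases[(start + 1L):(start + config$cgi_length)] <- isl
        cgi_rows[[length(cgi_rows) + 1L]] <-
          data.frame(chrom = chrom, start = start,
                     end = start + config$cgi_length, label = "CGI",
                     stringsAsFactors = FALSE)
      }
      chroms[chrom] <- paste(bases, collapse = "")
      # genes: alternate island-TSS and standalone placements
      free_slot <- config$cgi_per_chrom
      for (gk in seq_len(genes_per_chrom)) {
        if (gene_i >= config$n_genes) break
        gene_i <- gene_i + 1L
        id <- sprintf("gene%02d", gene_i)
        in_cgi <- gene_i <= n_cgi_genes
        strand <- if (gene_i %% 4 == 0) "-" else "+"
        if (in_cgi) {
          isl_k <- ((gk - 1L) %% config$cgi_per_chrom)
          tss_area <- isl_k * slot + 2000L + 150L
        } else {
          if (free_slot >= n_slots) break
          tss_area <- free_slot * slot + 2000L
          free_slot <- free_slot + 1L
        }
        if (strand == "+") {
          tss <- tss_area
          exons <- rbind(c(tss, tss + 300L), c(tss + 800L, tss + 1100L))
          utr5 <- rbind(c(tss, tss + 100L))
        } else {
          tss <- tss_area + 1099L
          exons <- rbind(c(tss_area, tss_area + 300L),
                         c(tss_area + 800L, tss_area + 1100L))
          utr5 <- rbind(c(tss_area + 1000L, tss_area + 1100L))
        }
        genes[[length(genes) + 1L]] <- gene_model(id, chrom, strand, tss,
                                                  exons, utr5)
      }
    }
    cgis <- do.call(rbind, cgi_rows)
    if (is.null(cgis)) cgis <- region_set() else
      class(cgis) <- c("RegionSet", "data.frame")
    list(genome = genome_sequence(chroms), cgis = cgis, genes = genes)
  })
}

#' Simulate the pedigreed 20-sample design
#'
#' Two native-breed pedigrees of four males each (three 9-year-olds, three
#' 4-year-olds and two 1-year-olds overall, with explicit sire links and
#' unobserved dams) plus four unrelated 7-month commercial-breed founders
#' (two of each sex). Muscle is sampled from all twelve individuals and
#' testis from the eight native-breed males: 20 samples.
#'
#' @param config A [sim_config()] (only the seed is used; the design is
#'   the study layout itself).
#' @return Sample-sheet `data.frame`.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  ind <- data.frame(
    individual_id = c("F1", "M1A", "M1B", "Y1",
                      "F2", "F2S", "M2A", "Y2",
                      "L1", "L2", "L3", "L4"),
    breed = c(rep("BMX", 8), rep("LW", 4)),
    age_years = c(9, 4, 4, 1, 9, 9, 4, 1, rep(7 / 12, 4)),
    sex = c(rep("M", 8), "M", "M", "F", "F"),
    pedigree_id = c(rep("ped1", 4), rep("ped2", 4), rep("pedLW", 4)),
    sire_id = c(NA, "F1", "F1", "M1A",
                "P2", "P2", "F2", "M2A",
                NA, NA, NA, NA),
    dam_id = c(NA, "D1", "D1", "D1B",
               "Q2", "Q2", "D2", "D2B",
               NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  mk <- function(tissue, rows) {
    data.frame(sample_id = paste0(substr(tissue, 1, 3), "_",
                                  rows$individual_id),
               tissue = tissue, rows, stringsAsFactors = FALSE)
  }
  sheet <- rbind(mk("muscle", ind),
                 mk("testis", ind[ind$breed == "BMX", ]))
  rownames(sheet) <- NULL
  validate_sample_sheet(sheet)
}

# Locate, inside planted islands, runs of >= min_cpgs plus-strand CpGs
# spanning <= window_bp; returns up to n windows as site-index lists.
.find_dense_windows <- function(sites, cgis, n, window_bp, min_cpgs) {
  out <- list()
  for (k in seq_len(nrow(cgis))) {
    if (length(out) >= n) break
    sel <- which(sites$chrom == cgis$chrom[k] &
                   sites$pos >= cgis$start[k] & sites$pos < cgis$end[k])
    plus <- sel[sites$strand[sel] == "+"]
    if (length(plus) < min_cpgs) next
    pos <- sites$pos[plus]
    for (i in seq_len(length(plus) - min_cpgs + 1L)) {
      j <- i + min_cpgs - 1L
      if (pos[j] - pos[i] <= window_bp) {
        run <- plus[i:j]
        # include the matching minus-strand records of the same CpGs
        mates <- which(sites$chrom == cgis$chrom[k] & sites$strand == "-" &
                         sites$pos %in% (pos[i:j] + 1L))
        out[[length(out) + 1L]] <- c(run, mates)
        break
      }
    }
  }
  out
}

#' Simulate WGBS count matrices with planted effects
#'
#' Generative model, mirroring the analysis model: per site i and sample j,
#' `logit pi_ij = mu_i + planted effects + g_ij` with
#' `g_.j ~ N(0, sigma2 K)` from the pedigree kinship;
#' `total_ij ~ NegBin(mean_coverage, dispersion)` truncated at 1; and
#' `meth_ij ~ BetaBinomial(total_ij, pi_ij, concentration)`. Baseline
#' `mu_i` comes from the island-low / background-high logit-normal
#' mixture. Pedigree-shared windows are planted inside islands (where CpGs
#' are dense enough); tissue, age, breed and sex effects are planted on
#' disjoint random site sets. When `genes` are supplied, coupled-candidate
#' genes additionally receive a per-sample promoter methylation shift so
#' that promoter levels vary across samples.
#'
#' @param genome,cgis,genes Output of [simulate_genome()] (`genes` may be
#'   `NULL`).
#' @param samples Sample sheet from [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return List: `matrix` (`MethCountMatrix`), `truth` (planted-signal
#'   tables: `tissue`, `age`, `breed`, `sex`, `pedigree_windows`,
#'   `pedigree_sites`, `coupled_candidates`, `promoter_meth`).
#' @export
simulate_methylomes <- function(genome, cgis, samples,
                                config = sim_config(), genes = NULL) {
  if (config$sigma2 < 0) stop("sigma2 must be >= 0")
  .with_stream(config$seed, "methylome", {
    sites <- cpg_sites_from_genome(genome, strands = config$strands)
    ns <- nrow(sites); n <- nrow(samples)
    in_cgi <- rep(FALSE, ns)
    for (k in seq_len(nrow(cgis))) {
      in_cgi <- in_cgi | (sites$chrom == cgis$chrom[k] &
                            sites$pos >= cgis$start[k] &
                            sites$pos < cgis$end[k])
    }
    base_mean <- ifelse(in_cgi, config$cgi_low_mean,
                        config$noncgi_high_mean)
    mu <- stats::rnorm(ns, stats::qlogis(base_mean), config$mu_sd)
    eta <- matrix(mu, ns, n)
    # pedigree-shared windows (inside islands, where CpGs are dense)
    pwin <- .find_dense_windows(sites, cgis, config$n_pedigree_windows,
                                config$pedigree_window_bp,
                                config$pedigree_window_min_cpgs)
    ped_sites <- unlist(pwin)
    ped_dir <- ifelse(samples$pedigree_id == "ped1", 1,
                      ifelse(samples$pedigree_id == "ped2", -1, 0))
    if (length(ped_sites)) {
      eta[ped_sites, ] <- 0  # neutral baseline for clean separation
      eta[ped_sites, ] <- eta[ped_sites, ] +
        matrix(ped_dir * config$pedigree_delta, length(ped_sites), n,
               byrow = TRUE)
    }
    avail <- setdiff(seq_len(ns), ped_sites)
    # Planted differential sites must satisfy the field's DMC notion: the
    # implied level-scale difference reaches 0.3. A site is eligible for a
    # given logit shift if at least one direction achieves that; the sign
    # is drawn among achieving directions.
    take <- function(k, delta_eff) {
      d_plus <- abs(stats::plogis(mu[avail] + delta_eff) -
                      stats::plogis(mu[avail]))
      d_minus <- abs(stats::plogis(mu[avail] - delta_eff) -
                       stats::plogis(mu[avail]))
      elig <- avail[pmax(d_plus, d_minus) >= 0.3]
      k <- min(k, length(elig))
      picked <- sort(sample(elig, k))
      dp <- abs(stats::plogis(mu[picked] + delta_eff) -
                  stats::plogis(mu[picked])) >= 0.3
      dm <- abs(stats::plogis(mu[picked] - delta_eff) -
                  stats::plogis(mu[picked])) >= 0.3
      sign <- ifelse(dp & dm, sample(c(-1, 1), length(picked),
                                     replace = TRUE),
                     ifelse(dp, 1, -1))
      avail <<- setdiff(avail, picked)
      list(idx = picked, sign = sign)
    }
    age_range <- diff(range(samples$age_years))
    tt <- take(config$n_tissue_dmc, config$tissue_delta)
    aa <- take(config$n_age_dmc, config$age_slope * age_range)
    bb <- take(config$n_breed_dmc, config$breed_delta)
    ss <- take(config$n_sex_dmc, config$sex_delta)
    t_idx <- tt$idx; a_idx <- aa$idx; b_idx <- bb$idx; s_idx <- ss$idx
    t_sign <- tt$sign; a_sign <- aa$sign
    b_sign <- bb$sign; s_sign <- ss$sign
    is_testis <- as.numeric(samples$tissue == "testis")
    age_c <- samples$age_years - mean(samples$age_years)
    is_lw <- as.numeric(samples$breed == "LW")
    is_f <- as.numeric(samples$sex == "F")
    if (length(t_idx))
      eta[t_idx, ] <- eta[t_idx, ] +
        outer(t_sign * config$tissue_delta, is_testis)
    if (length(a_idx))
      eta[a_idx, ] <- eta[a_idx, ] +
        outer(a_sign * config$age_slope, age_c)
    if (length(b_idx))
      eta[b_idx, ] <- eta[b_idx, ] +
        outer(b_sign * config$breed_delta, is_lw)
    if (length(s_idx))
      eta[s_idx, ] <- eta[s_idx, ] +
        outer(s_sign * config$sex_delta, is_f)
    # coupled-candidate promoter variability
    coupled <- character(0); prom_sites <- list()
    if (!is.null(genes) && config$n_coupled_genes > 0) {
      proms <- promoter_windows(genes, genome = genome)
      free <- !(seq_len(ns) %in% ped_sites)
      counts <- vapply(seq_len(nrow(proms)), function(i)
        sum(free & sites$chrom == proms$chrom[i] &
              sites$pos >= proms$start[i] &
              sites$pos < proms$end[i]), integer(1))
      ok <- which(counts >= config$min_promoter_cpgs)
      ok <- ok[order(-counts[ok])]
      pick <- utils::head(ok, config$n_coupled_genes)
      coupled <- proms$gene_id[pick]
      for (i in pick) {
        psites <- which(sites$chrom == proms$chrom[i] &
                          sites$pos >= proms$start[i] &
                          sites$pos < proms$end[i])
        # pedigree-window sites keep their planted pattern untouched
        psites <- setdiff(psites, ped_sites)
        if (!length(psites)) next
        prom_sites[[proms$gene_id[i]]] <- psites
        shift <- stats::rnorm(n, 0, config$promoter_variability)
        eta[psites, ] <- eta[psites, ] +
          matrix(shift, length(psites), n, byrow = TRUE)
      }
    }
    # genetic random effect g ~ N(0, sigma2 K) per site
    if (config$sigma2 > 0) {
      A <- kinship_from_pedigree(samples)
      K <- expand_kinship(A, samples)
      Lc <- chol(K + diag(1e-8, n))
      G <- sqrt(config$sigma2) *
        (matrix(stats::rnorm(ns * n), ns, n) %*% Lc)
      eta <- eta + G
    }
    pi <- stats::plogis(eta)
    # truncated negative-binomial coverage
    p0 <- stats::pnbinom(0, size = config$coverage_dispersion,
                         mu = config$mean_coverage)
    u <- stats::runif(ns * n, p0, 1)
    total <- stats::qnbinom(u, size = config$coverage_dispersion,
                            mu = config$mean_coverage)
    total <- matrix(as.integer(total), ns, n)
    if (is.finite(config$bb_concentration)) {
      c0 <- config$bb_concentration
      pshift <- stats::rbeta(ns * n, c(pi) * c0, (1 - c(pi)) * c0)
      # guard against numeric under/overflow at extreme pi
      pshift <- pmin(pmax(pshift, 0), 1)
      meth <- matrix(stats::rbinom(ns * n, c(total), pshift), ns, n)
    } else {
      meth <- matrix(stats::rbinom(ns * n, c(total), c(pi)), ns, n)
    }
    mat <- meth_count_matrix(sites, samples$sample_id, meth, total)
    site_key <- function(idx)
      data.frame(sites[idx, , drop = FALSE], row.names = NULL)
    lvl <- function(idx, sign, delta)
      abs(stats::plogis(mu[idx] + sign * delta) - stats::plogis(mu[idx]))
    truth <- list(
      tissue = if (length(t_idx)) data.frame(site_key(t_idx),
        direction = ifelse(t_sign > 0, "up", "down"),
        delta_logit = t_sign * config$tissue_delta,
        level_diff = lvl(t_idx, t_sign, config$tissue_delta)) else NULL,
      age = if (length(a_idx)) data.frame(site_key(a_idx),
        direction = ifelse(a_sign > 0, "up", "down"),
        slope_logit = a_sign * config$age_slope) else NULL,
      breed = if (length(b_idx)) data.frame(site_key(b_idx),
        direction = ifelse(b_sign > 0, "up", "down"),
        delta_logit = b_sign * config$breed_delta) else NULL,
      sex = if (length(s_idx)) data.frame(site_key(s_idx),
        direction = ifelse(s_sign > 0, "up", "down"),
        delta_logit = s_sign * config$sex_delta) else NULL,
      pedigree_windows = if (length(pwin)) do.call(rbind,
        lapply(seq_along(pwin), function(w) {
          idx <- pwin[[w]]
          data.frame(window = w, chrom = sites$chrom[idx[1]],
                     start = min(sites$pos[idx]),
                     end = max(sites$pos[idx]) + 1L,
                     n_sites = length(idx))
        })) else NULL,
      pedigree_sites = if (length(ped_sites)) site_key(ped_sites) else NULL,
      coupled_candidates = coupled,
      promoter_meth = if (length(prom_sites)) {
        pm <- t(vapply(names(prom_sites), function(g)
          colMeans(pi[prom_sites[[g]], , drop = FALSE]), numeric(n)))
        colnames(pm) <- samples$sample_id
        pm
      } else NULL)
    list(matrix = mat, truth = truth)
  })
}

#' Simulate expression coupled to promoter methylation
#'
#' For coupled genes, `log(FPKM + 1) = a + b m + eps` with `m` the gene's
#' true promoter mean methylation per sample, `|b|` the coupling slope and
#' alternating signs; uncoupled genes get independent noise around the
#' same intercept. FPKM values are floored at 0.
#'
#' @param genes Gene model list.
#' @param promoter_meth Gene x sample matrix of true promoter methylation
#'   (from `truth$promoter_meth` of [simulate_methylomes()]).
#' @param config A [sim_config()].
#' @param coupled Character vector of coupled gene ids; defaults to the
#'   rows of `promoter_meth`. Requested genes missing from it (no
#'   simulated promoter CpGs) raise an error listing them.
#' @return List: `expr` (genes x samples FPKM matrix), `truth`
#'   (`data.frame` gene_id, sign, slope).
#' @export
simulate_expression <- function(genes, promoter_meth,
                                config = sim_config(), coupled = NULL) {
  if (is.null(coupled)) coupled <- rownames(promoter_meth)
  missing <- setdiff(coupled, rownames(promoter_meth))
  if (length(missing))
    stop("coupled gene(s) without promoter CpGs: ",
         paste(missing, collapse = ", "))
  .with_stream(config$seed, "expression", {
    ids <- vapply(genes, function(g) g$gene_id, "")
    n <- ncol(promoter_meth)
    expr <- matrix(0, length(ids), n,
                   dimnames = list(ids, colnames(promoter_meth)))
    signs <- rep_len(c(1, -1), length(coupled))
    for (k in seq_along(coupled)) {
      g <- coupled[k]
      m <- promoter_meth[g, ]
      lf <- config$coupling_intercept +
        signs[k] * config$coupling_slope * m +
        stats::rnorm(n, 0, config$expression_noise_sd)
      expr[g, ] <- pmax(expm1(lf), 0)
    }
    for (g in setdiff(ids, coupled)) {
      lf <- config$coupling_intercept +
        stats::rnorm(n, 0, config$uncoupled_sd)
      expr[g, ] <- pmax(expm1(lf), 0)
    }
    list(expr = expr,
         truth = data.frame(gene_id = coupled, sign = signs,
                            slope = config$coupling_slope,
                            stringsAsFactors = FALSE))
  })
}

#' Run the full simulation
#'
#' Convenience wrapper chaining [simulate_genome()], [simulate_pedigree()],
#' [simulate_methylomes()] and [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @return List: `genome`, `cgis`, `genes`, `samples`, `matrix`, `truth`,
#'   `expr`, `expr_truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  gen <- simulate_genome(config)
  samples <- simulate_pedigree(config)
  meth <- simulate_methylomes(gen$genome, gen$cgis, samples, config,
                              genes = gen$genes)
  ex <- if (!is.null(meth$truth$promoter_meth))
    simulate_expression(gen$genes, meth$truth$promoter_meth, config)
  else list(expr = NULL, truth = NULL)
  list(genome = gen$genome, cgis = gen$cgis, genes = gen$genes,
       samples = samples, matrix = meth$matrix, truth = meth$truth,
       expr = ex$expr, expr_truth = ex$truth, config = config)
}

#' Write a simulated study to pipeline input files
#'
#' Emits exactly the pipeline's input formats: genome FASTA, gene GTF,
#' per-sample bedGraph count files, sample-sheet TSV, expression TSV, and
#' truth BEDs for planted islands and pedigree windows.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisible named list of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    sheet = file.path(dir, "samples.tsv"),
    expr = file.path(dir, "expression.tsv"),
    cgi_truth = file.path(dir, "truth_cgis.bed"))
  write_fasta(sim$genome, paths$genome)
  write_gtf_minimal(sim$genes, paths$gtf)
  write_sample_sheet(sim$samples, paths$sheet)
  if (!is.null(sim$expr)) write_expression(sim$expr, paths$expr)
  write_regions_bed(sim$cgis, paths$cgi_truth)
  counts_dir <- file.path(dir, "counts")
  dir.create(counts_dir, showWarnings = FALSE)
  for (id in sim$matrix$samples) {
    p <- file.path(counts_dir, paste0(id, ".bedGraph"))
    write_methyldackel_bedgraph(sim$matrix, id, p)
    paths[[paste0("counts_", id)]] <- p
  }
  if (!is.null(sim$truth$pedigree_windows)) {
    p <- file.path(dir, "truth_pedigree_windows.bed")
    pw <- sim$truth$pedigree_windows
    write_regions_bed(region_set(pw$chrom, pw$start, pw$end,
                                 paste0("pedwin", pw$window)), p)
    paths$pedigree_truth <- p
  }
  invisible(paths)
}
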