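test_that("observed/expected CpG ratio follows the counting definition", {
  expect_equal(obs_exp_ratio("CGCGCGCG"), 2.0)
  expect_equal(obs_exp_ratio("AATT"), 0)
  expect_equal(obs_exp_ratio("CATG"), 0)
  expect_error(obs_exp_ratio(""), "non-empty")
  # N bases excluded from all counts
  expect_equal(obs_exp_ratio("CGNNCG"), 2 * 4 / 4)
})

test_that("island detection equals brute-force window enumeration", {
  set.seed(71)
  # planted CG-repeat flanked by poly-A
  seq <- paste0(strrep("A", 1000), strrep("CG", 150), strrep("A", 1000))
  g <- genome_sequence(c(c1 = seq))
  det <- detect_cgis(g)
  bf <- brute_cgis(seq)
  expect_equal(nrow(det), nrow(bf))
  expect_equal(det$start, bf[, 1])
  expect_equal(det$end, bf[, 2])
  # detection covers the planted repeat, extending < window beyond it
  expect_true(det$start[1] >= 1000 - 199 && det$start[1] <= 1000)
  expect_true(det$end[1] <= 1300 + 199 && det$end[1] >= 1300)
  # a mixed random chromosome agrees too
  bases <- sample(c("A", "C", "G", "T"), 3000, replace = TRUE,
                  prob = c(.2, .3, .3, .2))
  seq2 <- paste(bases, collapse = "")
  g2 <- genome_sequence(c(c1 = seq2))
  det2 <- detect_cgis(g2)
  bf2 <- brute_cgis(seq2)
  if (is.null(bf2)) {
    expect_equal(nrow(det2), 0)
  } else {
    expect_equal(det2$start, bf2[, 1])
    expect_equal(det2$end, bf2[, 2])
  }
})

test_that("island criterion boundaries are strict", {
  # all-A chromosome: no islands
  g <- genome_sequence(c(c1 = strrep("A", 2000)))
  expect_equal(nrow(detect_cgis(g)), 0)
  # a 200-bp chromosome that is pure CG repeat: the single qualifying
  # window unions to exactly 200 bp, which the strict > 200 filter rejects
  g2 <- genome_sequence(c(c1 = strrep("CG", 100)))
  expect_equal(nrow(detect_cgis(g2)), 0)
  # relaxing the length threshold by one base admits it
  expect_equal(nrow(detect_cgis(g2, min_len = 199)), 1)
  # chromosomes shorter than the window are skipped, not fatal
  g3 <- genome_sequence(c(tiny = "ACGT", c1 = strrep("A", 500)))
  expect_message(det3 <- detect_cgis(g3), "skipped")
  expect_equal(nrow(det3), 0)
})

test_that("island, shore, shelf bands partition sites at half-open edges", {
  cgis <- region_set("c1", 10000L, 10600L, "CGI")
  pos <- c(10200L,                 # inside
           10600L + 1999L - 1L,    # d = 1999 -> shore
           10600L + 2000L - 1L,    # d = 2000 -> shelf
           10600L + 4001L - 1L,    # d = 4001 -> open sea
           10000L - 2000L,         # d = 2000 upstream -> shelf
           10000L - 1L)            # d = 1 -> shore
  sites <- data.frame(chrom = "c1", pos = pos, strand = "+")
  cls <- classify_island_context(sites, cgis)
  expect_equal(as.character(cls),
               c("CGI", "shore", "shelf", "open_sea", "shelf", "shore"))
  # partition: exactly one class per site, never NA
  expect_false(anyNA(cls))
})

test_that("genic classification follows UTR > exon > intron precedence", {
  gA <- gene_model("gA", "c1", "+", 100L,
                   rbind(c(100L, 300L), c(500L, 700L)),
                   rbind(c(100L, 180L)))
  gB <- gene_model("gB", "c1", "+", 50L, rbind(c(50L, 900L)))
  sites <- data.frame(chrom = "c1",
                      pos = c(150L,  # 5'UTR of gA (also exon of gB)
                              250L,  # exon of gA
                              400L,  # intron of gA but exon of gB -> exon
                              950L,  # outside both -> intergenic
                              120L), # UTR wins over everything
                      strand = "+")
  cls <- classify_genic_context(sites, list(gA, gB))
  expect_equal(as.character(cls),
               c("five_prime_UTR", "exon", "exon", "intergenic",
                 "five_prime_UTR"))
  # intron requires being in a span but in no exon of any gene
  cls2 <- classify_genic_context(data.frame(chrom = "c1", pos = 400L,
                                            strand = "+"), list(gA))
  expect_equal(as.character(cls2), "intron")
})

test_that("promoter windows follow the -800/+200 convention per strand", {
  gp <- gene_model("gp", "c1", "+", 1000L, rbind(c(1000L, 1400L)))
  w <- promoter_window(gp)
  expect_equal(c(w$start, w$end), c(200L, 1200L))
  gm <- gene_model("gm", "c1", "-", 1000L, rbind(c(600L, 1001L)))
  wm <- promoter_window(gm)
  expect_equal(c(wm$start, wm$end), c(801L, 1801L))
  # clipping at the chromosome start
  gc <- gene_model("gc", "c1", "+", 100L, rbind(c(100L, 300L)))
  wc <- promoter_window(gc)
  expect_equal(c(wc$start, wc$end), c(0L, 300L))
})

test_that("planted islands are recovered from the simulated genome", {
  sim <- study_sim()
  det <- detect_cgis(sim$genome)
  for (i in seq_len(nrow(sim$cgis))) {
    ov <- det[det$chrom == sim$cgis$chrom[i] &
                det$start < sim$cgis$end[i] &
                det$end > sim$cgis$start[i], ]
    expect_gte(nrow(ov), 1)
    inter <- min(ov$end[1], sim$cgis$end[i]) -
      max(ov$start[1], sim$cgis$start[i])
    uni <- max(ov$end[1], sim$cgis$end[i]) -
      min(ov$start[1], sim$cgis$start[i])
    expect_gte(inter / uni, 0.5)
  }
})

test_that("CpG enumeration records both strands as distinct sites", {
  g <- genome_sequence(c(c1 = "ACGTTCGA"))
  s <- cpg_sites_from_genome(g)
  expect_equal(nrow(s), 4)  # two CG occurrences x two strands
  expect_equal(s$pos[s$strand == "+"], c(1L, 5L))
  expect_equal(s$pos[s$strand == "-"], c(2L, 6L))
  sp <- cpg_sites_from_genome(g, strands = "plus")
  expect_equal(nrow(sp), 2)
})

test_that("site context table combines all classification axes", {
  sim <- study_sim()
  sub <- sim$matrix$sites[1:500, ]
  ctx <- cpg_context(sub, sim$cgis, sim$genes)
  expect_equal(nrow(ctx), 500)
  expect_false(anyNA(ctx$island_class))
  expect_false(anyNA(ctx$genic_class))
  # the compound flag is the conjunction of its two axes
  expect_equal(ctx$utr5_cgi,
               ctx$island_class == "CGI" &
                 ctx$genic_class == "five_prime_UTR")
})
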