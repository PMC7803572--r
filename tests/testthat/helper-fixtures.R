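# Shared fixtures, built in code. The default study simulation is cached
# per test run; seed 1 is the package-wide fixture convention.

.fixture_env <- new.env(parent = emptyenv())

study_sim <- function(seed = 1) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_study(sim_config(seed = seed))
  .fixture_env[[key]]
}

null_sim <- function(seed = 1) {
  key <- paste0("null_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_study(sim_config(
      seed = seed, n_tissue_dmc = 0, n_age_dmc = 0, n_breed_dmc = 0,
      n_sex_dmc = 0, n_pedigree_windows = 0, n_coupled_genes = 0))
  .fixture_env[[key]]
}

site_key <- function(s) paste(s$chrom, s$pos, s$strand)

# A tiny hand-built count matrix: 4 sites x 4 samples.
toy_matrix <- function() {
  sites <- data.frame(chrom = c("c1", "c1", "c1", "c2"),
                      pos = c(10L, 100L, 700L, 5L),
                      strand = "+")
  meth <- matrix(c(3L, 5L, 0L, 2L,
                   1L, NA, 10L, 2L,
                   0L, 0L, 0L, 0L,
                   9L, 9L, 9L, 9L), 4, 4, byrow = TRUE)
  total <- matrix(c(4L, 10L, 12L, 20L,
                    30L, NA, 15L, 9L,
                    400L, 5L, 50L, 12L,
                    10L, 10L, 10L, 10L), 4, 4, byrow = TRUE)
  meth_count_matrix(sites, paste0("s", 1:4), meth, total)
}

toy_sheet <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             individual_id = paste0("i", 1:4),
             tissue = c("muscle", "muscle", "testis", "testis"),
             breed = "B", age_years = c(1, 4, 1, 4), sex = "M",
             pedigree_id = "p1", sire_id = NA, dam_id = NA,
             stringsAsFactors = FALSE)
}
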