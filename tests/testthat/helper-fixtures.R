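# shared fixtures: random-sequence helper, a cached mid-size simulated
# pair and a lazily computed full screen of it

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.fixture_env <- new.env(parent = emptyenv())

# default-parameter synthetic pair used by the parameter-recovery tests
get_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_mito_pair(seed = 1)
  }
  .fixture_env$sim
}

# small fast pair for structural tests
get_mini_sim <- function() {
  if (is.null(.fixture_env$mini)) {
    .fixture_env$mini <- generate_pair(sim_params(
      genome_length = 30000, n_blocks = 6, n_unique_regions = 4,
      n_genes = 10, n_trna = 4, n_rrna = 1,
      short_repeat_lengths = c(300L, 150L, 90L),
      large_repeat_length = 1200, n_snps_in_genes = 5, n_snp_genes = 3,
      seed = 11))
  }
  .fixture_env$mini
}

get_screen <- function() {
  if (is.null(.fixture_env$screen)) {
    sim <- get_sim()
    .fixture_env$screen <- run_screen(
      sim$cms, sim$normal,
      cms_annotations = sim$cms_annotations,
      normal_annotations = sim$normal_annotations)
  }
  .fixture_env$screen
}
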