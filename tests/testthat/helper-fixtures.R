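# Shared small fixtures, generated in code.

# Compact study: 2 cohorts x 40 samples, 6 cell types, strong planted signal.
small_sim_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(n_cohorts = 2L, samples_per_cohort = 40L, n_genes = 120L,
         n_cell_types = 6L, genes_per_set = 8L, n_true_pairs = 3L,
         pair_log_hazard = 1.0, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# Random expression sample as a named vector.
random_sample <- function(n_genes, seed) {
  set.seed(seed)
  stats::setNames(rnorm(n_genes, 6, 2), sprintf("g%03d", seq_len(n_genes)))
}

# Censored 8-subject survival fixture used by several hand-checked tests.
surv8 <- list(time = c(3, 5, 5, 8, 10, 12, 15, 18),
              event = c(1, 1, 0, 1, 0, 1, 1, 0))
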