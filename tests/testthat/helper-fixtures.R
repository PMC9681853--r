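# Small cohorts used across unit tests (full default-size cohorts are
# exercised by the acceptance suite).

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_cancers = 3L, n_healthy = 10L, n_tumor = 10L, n_genes = 60L,
    n_gene_sets = 4L, set_size_range = c(5L, 15L), rng_seed = seed
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

small_cohort <- function(seed = 1L, ...) {
  generate_cohort(small_config(seed, ...))
}

null_config <- function(seed = 1L, ...) {
  small_config(seed,
    focal_downshift = 0, aneuploidy_coupling = 0,
    focal_depletion_factor = 1, rewiring_weight = 0, oe_factor = 1, ...
  )
}
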