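# Small cohorts shared across test files, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(sim_config(
      n_genes = 60, n_dynamic_genes = 8, n_de_genes = 8,
      n_subjects_per_group = 4, n_cells_per_subject = 50,
      cell_types = c("excitatory", "astrocyte"), seed = 101
    ))
  }
  .fixture_env$small
}

# cohort plus the velocity pipeline applied to it (stochastic fit)
small_velocity <- function() {
  if (is.null(.fixture_env$small_vel)) {
    ds <- small_cohort()
    norm <- normalize_counts(ds$counts, "velocity_layers")
    mom <- neighbor_moments(norm$S, norm$U, n_pcs = 10, k = 30)
    fit <- fit_gamma(mom, "stochastic")
    V <- compute_velocity(mom, fit)
    .fixture_env$small_vel <- list(ds = ds, norm = norm, mom = mom,
                                   fit = fit, V = V)
  }
  .fixture_env$small_vel
}

# brute-force Mann-Whitney U with average ranks, for one grouping
u_stat_oracle <- function(x, g1) {
  r <- rank(x)
  sum(r[g1]) - sum(g1) * (sum(g1) + 1) / 2
}
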