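# Small-scale scenario used by fast unit tests: same model, reduced K and
# generation count so a replicate runs in well under a second.
small_params <- function(...) {
  args <- modifyList(list(carrying_capacity_per_species = 100L,
                          n_generations = 25L, snapshot_interval = 25L),
                     list(...))
  do.call(sim_params, args)
}

# Exhaustive-enumeration oracle for the paired one-sided signed-rank test
# (alternative: x > y). Valid for small n without zero differences; ties are
# handled by mid-ranks and enumeration of all 2^n sign assignments.
wilcoxon_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mean(w_all >= w_obs)
}

# The full-scale study grid shared by the acceptance tests: eight scenarios,
# 12 replicates each, 500 generations at K = 800. Computed once per test run
# and memoized (several criteria read different summaries of the same runs).
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_grid_results <- function() {
  if (is.null(.acceptance_cache$results)) {
    .acceptance_cache$results <- run_experiment(
      default_scenario_grid(), n_replicates = 12, base_seed = 1
    )
  }
  .acceptance_cache$results
}
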