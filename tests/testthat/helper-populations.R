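# shared fixtures, all built in code

# hand-made moment summary for closed-form arithmetic checks
make_ms <- function(dmu, S, T, dtheta = 1) {
  S <- as.matrix(S)
  structure(
    list(mu_plus = dmu * dtheta / 2, mu_minus = -dmu * dtheta / 2,
         S_plus = S, S_minus = S, S_pooled = S,
         dmu_dtheta = dmu, n_trials = as.integer(T),
         n_neurons = length(dmu), dtheta = dtheta),
    class = "moment_summary")
}

# Monte-Carlo mean of an estimator over replicate experiments
mc_estimates <- function(pop, T, nrep, fun, seed_tag) {
  vapply(seq_len(nrep), function(r)
    fun(simulate_experiment(pop, T, seed = derive_seed(seed_tag, T, r))),
    numeric(1))
}

bc_value <- function(ts) bc_info(ts, warn_noisy = FALSE)$value

# a small correlated trial set for invariance checks
small_correlated_ts <- function(N = 6, T = 40, seed = 5, dtheta = 2) {
  simulate_experiment(example_gaussian_population(N, dtheta, seed = seed),
                      T, seed = derive_seed(seed, 99))
}

# internal RNG-scoping helper, reused directly by the tests
withr_seed <- fisherbc:::withr_seed
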