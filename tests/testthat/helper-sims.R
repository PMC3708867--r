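# Shared simulation fixtures, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

# canonical wild-type equilibrium run reused across distribution,
# statistics and acceptance tests
wt_equilibrium_sim <- function() {
  if (is.null(.sim_cache$wt))
    .sim_cache$wt <- simulate_population(n_initial = 400, n_cap = 2000,
                                         t_end = 150, seed = 1)
  .sim_cache$wt
}

# random valid transition specs for property tests: equilibrium fractions
# bounded away from zero, shuttle loads rescaled so all staying
# probabilities remain positive
random_spec <- function() {
  z <- runif(4, 0.05, 1)
  z <- z / sum(z)
  w <- matrix(0, 4, 4)
  for (pr in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
    w[pr[1], pr[2]] <- w[pr[2], pr[1]] <- runif(1, 0.01, 0.2)
  load <- max(rowSums(w / 2) / z)
  if (load > 0.9) w <- w * 0.9 / load
  transition_spec(z_star = z, shuttle = w, t_d = runif(1, 5, 20))
}
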