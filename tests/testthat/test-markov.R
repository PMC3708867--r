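test_that("transition probabilities implement the detailed-balance construction", {
  spec <- transition_spec()
  p <- transition_probabilities(spec)
  # half of the 12% two-way shuttle, over the 14% resident fraction
  expect_equal(p[1, 2], 0.06 / 0.14, tolerance = 1e-12)
  expect_equal(unname(p["1", "4"]), 0)
  expect_equal(unname(p["4", "1"]), 0)
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # detailed balance holds exactly as constructed
  z <- spec$z_star
  expect_equal(outer(z, rep(1, 4)) * p, t(outer(z, rep(1, 4)) * p),
               tolerance = 1e-14)
})

test_that("no switching yields the identity chain", {
  spec <- transition_spec(shuttle = matrix(0, 4, 4))
  p <- transition_probabilities(spec)
  expect_equal(unname(p), diag(4))
  k <- transition_rate_matrix(p, spec$t_d)
  expect_equal(unname(k), matrix(0, 4, 4))
})

test_that("overloaded shuttle fractions are rejected with the offending row", {
  spec <- transition_spec(shuttle = list(`1-2` = 0.40))
  expect_error(transition_probabilities(spec), "row")
  expect_error(transition_spec(shuttle = list(`1-4` = 0.1)), "not linked")
  expect_error(transition_spec(z_star = c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
})

test_that("rates are per-cycle probabilities over the doubling time", {
  spec <- transition_spec()
  p <- transition_probabilities(spec)
  k <- transition_rate_matrix(p, 10)
  expect_equal(k[1, 2], (0.06 / 0.14) / 10, tolerance = 1e-12)
  expect_equal(unname(rowSums(k)), rep(0, 4), tolerance = 1e-12)
  expect_true(all(k[row(k) != col(k)] >= 0))
  expect_error(transition_rate_matrix(p, -1), "t_d")
})

test_that("all states share the proliferation rate ln2 / t_d", {
  expect_equal(growth_rates(10), rep(log(2) / 10, 4))
  expect_equal(growth_rates(log(2)), rep(1, 4))
  # a population at this rate doubles over one doubling time
  expect_equal(exp(growth_rates(10)[1] * 10), 2)
})

test_that("stationary composition recovers the input equilibrium", {
  rm_ <- rate_matrices(transition_spec())
  expect_equal(stationary_composition(rm_$k), c(0.14, 0.28, 0.28, 0.30),
               tolerance = 1e-10)
  expect_error(stationary_composition(matrix(0, 4, 4)), "null space")
})

test_that("round-trip: stationary of the built chain equals z_star for random specs", {
  set.seed(42)
  for (i in 1:25) {
    spec <- random_spec()
    zs <- stationary_composition(rate_matrices(spec)$k)
    expect_equal(zs, spec$z_star, tolerance = 1e-8)
  }
})

test_that("long-run occupancy of a simulated single cell matches the stationary law", {
  # brute-force continuous-time chain simulation as an independent oracle
  set.seed(7)
  k <- rate_matrices(transition_spec())$k
  occupancy <- numeric(4)
  state <- 1L
  t_total <- 0
  while (t_total < 1e6) {
    exit <- -k[state, state]
    stay <- rexp(1, exit)
    occupancy[state] <- occupancy[state] + stay
    t_total <- t_total + stay
    probs <- k[state, ]
    probs[state] <- 0
    state <- sample.int(4L, 1L, prob = probs)
  }
  expect_equal(occupancy / sum(occupancy), c(0.14, 0.28, 0.28, 0.30),
               tolerance = 0.05)
})

test_that("fraction dynamics: stationarity, convergence and conservation", {
  rm_ <- rate_matrices(transition_spec())
  zs <- stationary_composition(rm_$k)
  expect_equal(unname(evolve_fractions(zs, rm_, 37)), zs, tolerance = 1e-9)
  # a pure biallelic ensemble re-blends within 100 h
  z100 <- evolve_fractions(c(1, 0, 0, 0), rm_, 100)
  expect_lt(max(abs(z100 - zs)), 0.01)
  # conservation of total fraction at arbitrary times
  zz <- evolve_fractions(c(0.6, 0.1, 0.1, 0.2), rm_, c(0.5, 3, 17, 64))
  expect_equal(unname(rowSums(zz)), rep(1, 4), tolerance = 1e-9)
})

test_that("matrix-exponential propagation matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  rm_ <- rate_matrices(transition_spec())
  z0 <- c(1, 0, 0, 0)
  rhs <- function(t, z, p) list(as.numeric(z %*% rm_$k))
  sol <- deSolve::ode(z0, c(0, 25, 50, 100), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  for (i in 2:4) {
    expect_equal(unname(evolve_fractions(z0, rm_, sol[i, 1])),
                 unname(sol[i, 2:5]), tolerance = 1e-6)
  }
})

test_that("distance to equilibrium is non-increasing after early transients", {
  rm_ <- rate_matrices(transition_spec())
  zs <- stationary_composition(rm_$k)
  tt <- seq(10, 150, by = 5)
  dev <- apply(evolve_fractions(c(1, 0, 0, 0), rm_, tt), 1,
               function(z) sqrt(sum((z - zs)^2)))
  expect_true(all(diff(dev) <= 1e-12))
})
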