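test_that("cell size grows exponentially and doubles per cycle", {
  expect_equal(grow_size(0.3, 0, 10), 0.3)
  expect_equal(grow_size(0.3, 10, 10), 0.6)
  expect_equal(grow_size(0.2325, 10, 10), 0.465)
})

test_that("division hazard follows the Gaussian division-size law", {
  dp <- division_params()
  # at the mean division size: r_v * phi / S with S = 1/2
  expect_equal(division_hazard(0.465, 10, dp), 0.247278, tolerance = 1e-5)
  expect_lt(division_hazard(1e-4, 10, dp), 1e-7)
  # hazard of a Gaussian stopping law increases through the bulk
  vv <- seq(dp$mu - 2 * dp$sigma, dp$mu + 3 * dp$sigma, length.out = 200)
  expect_true(all(diff(division_hazard(vv, 10, dp)) > 0))
  # survival underflow is capped, not infinite
  expect_equal(division_hazard(5, 10, dp), 50)
})

test_that("partition fractions have symmetric-beta moments", {
  set.seed(5)
  x <- sample_partition_fraction(39, 1e5)
  expect_equal(mean(x), 0.5, tolerance = 0.002)
  expect_equal(sd(x), 0.5 / sqrt(2 * 39 + 1), tolerance = 0.01)
  # q -> infinity concentrates at an even split
  xx <- sample_partition_fraction(1e6, 1e4)
  expect_lt(sd(xx), 0.001)
})

test_that("division conserves every state component and the allelic pattern", {
  set.seed(9)
  mother <- list(n1 = 100, n2 = 2914.2, r1 = 3.5, r2 = 0, v = 0.47,
                 type = 4L)
  for (i in 1:200) {
    d <- divide_cell(mother)
    for (f in c("n1", "n2", "r1", "r2", "v"))
      expect_equal(d[[1]][[f]] + d[[2]][[f]], mother[[f]],
                   tolerance = 1e-13)
    expect_identical(d[[1]]$type, 4L)
    expect_identical(d[[2]]$type, 4L)
  }
  # daughter/mother ratio reproduces the beta moments
  set.seed(10)
  ratios <- vapply(1:1e4, function(i)
    divide_cell(mother)[[1]]$v / mother$v, numeric(1))
  expect_equal(mean(ratios), 0.5, tolerance = 0.01)
  expect_equal(sd(ratios), 0.0562, tolerance = 0.02)
})

test_that("event rate matrix rows hold switch channels plus division", {
  rm_ <- rate_matrices(transition_spec())
  pop <- list(type = 4L, v = 0.3)
  e <- build_event_rates(pop, rm_, "constant_rate")
  expect_equal(e$targets[1, ], 1:3)
  expect_equal(e$rates[1, ], c(0, rm_$k[4, 2], rm_$k[4, 3], log(2) / 10),
               tolerance = 1e-12)
  # no switching: total rate is the division rate alone
  rm0 <- rate_matrices(transition_spec(shuttle = matrix(0, 4, 4)))
  e0 <- build_event_rates(pop, rm0, "constant_rate")
  expect_equal(e0$total_rate, log(2) / 10, tolerance = 1e-12)
  # additivity over identical cells
  pop100 <- list(type = rep(4L, 100), v = rep(0.3, 100))
  e100 <- build_event_rates(pop100, rm_, "constant_rate")
  expect_equal(e100$total_rate, 100 * sum(e$rates[1, ]), tolerance = 1e-9)
  # size_hazard mode plugs in the hazard of each cell's size
  eh <- build_event_rates(pop, rm_, "size_hazard")
  expect_equal(eh$rates[1, 4], division_hazard(0.3, 10), tolerance = 1e-12)
  expect_error(build_event_rates(list(type = integer(0), v = numeric(0)),
                                 rm_), "extinct")
})

test_that("quiescence intervals are exponential with the summed rate", {
  set.seed(12)
  x <- vapply(1:1e5, function(i) sample_quiescence(2), numeric(1))
  expect_equal(mean(x), 0.5, tolerance = 0.01)
  set.seed(33); a <- sample_quiescence(0.7)
  set.seed(33); b <- sample_quiescence(0.7)
  expect_identical(a, b)
  expect_error(sample_quiescence(0), "total_rate")
})

test_that("event selection is a deterministic inverse-CDF lookup", {
  rm0 <- rate_matrices(transition_spec(shuttle = matrix(0, 4, 4)))
  e1 <- build_event_rates(list(type = 2L, v = 0.4), rm0, "constant_rate")
  for (r2 in c(0, 0.3, 0.999)) {
    sel <- select_event(e1, r2)
    expect_equal(sel$cell, 1L)
    expect_equal(sel$kind, "divide")
  }
  # two cells with equal single rates split the unit interval in half
  e2 <- build_event_rates(list(type = c(2L, 2L), v = c(0.4, 0.4)),
                          rm0, "constant_rate")
  expect_equal(select_event(e2, 0.25)$cell, 1L)
  expect_equal(select_event(e2, 0.75)$cell, 2L)
})

test_that("empirical event frequencies match the rate weights", {
  rm_ <- rate_matrices(transition_spec())
  e <- build_event_rates(list(type = c(1L, 4L), v = c(0.3, 0.55)),
                         rm_, "size_hazard")
  set.seed(14)
  n_draw <- 1e5
  picks <- matrix(0, 2, 4)
  u <- runif(n_draw)
  for (i in seq_len(n_draw)) {
    sel <- select_event(e, u[i])
    col <- if (sel$kind == "divide") 4L else
      which(e$targets[sel$cell, ] == sel$target)
    picks[sel$cell, col] <- picks[sel$cell, col] + 1
  }
  expect_equal(as.vector(picks / n_draw),
               as.vector(e$rates / e$total_rate), tolerance = 0.03)
  expect_lt(max(abs(picks / n_draw - e$rates / e$total_rate)), 0.01)
})
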