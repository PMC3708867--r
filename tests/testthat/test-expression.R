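gam <- log(2) / 2

test_that("allelic pattern maps to and from the four cell types", {
  expect_equal(pattern_type(TRUE, TRUE), 1L)
  expect_equal(pattern_type(TRUE, FALSE), 2L)
  expect_equal(pattern_type(FALSE, TRUE), 3L)
  expect_equal(pattern_type(FALSE, FALSE), 4L)
  al <- type_alleles(1:4)
  expect_equal(pattern_type(al[, 1], al[, 2]), 1:4)
  expect_error(type_alleles(5), "1..4")
})

test_that("allele production switches between full and leak rates", {
  pp <- expression_params()
  expect_equal(allele_production(TRUE, pp), 1000)
  expect_equal(allele_production(FALSE, pp), 10)
  expect_equal(allele_production(FALSE, pp, "reporter"), 10)
  p0 <- expression_params(s_off = 0)
  expect_equal(allele_production(FALSE, p0), 0)
  expect_error(expression_params(s_on = 5, s_off = 10), "s_on > s_off")
})

test_that("deterministic propagation is the exact closed form", {
  expect_equal(propagate_deterministic(123.4, 500, gam, 0), 123.4)
  # monoallelic steady state: one active + one leaky allele
  ss_mono <- steady_state(1010, gam)
  expect_equal(ss_mono, 2914.244, tolerance = 1e-6)
  expect_equal(propagate_deterministic(ss_mono, 1010, gam, 13.7), ss_mono)
  expect_equal(propagate_deterministic(0, 1010, gam, 1e3), ss_mono)
})

test_that("first passage below the positivity gate from the biallelic state", {
  ss_bi <- steady_state(2000, gam)   # 5770.8
  ss_off <- steady_state(20, gam)    # 57.7
  # closed-form inversion done by hand as the oracle
  t_star <- log((ss_bi - ss_off) / (500 - ss_off)) / gam
  expect_equal(t_star, 7.3825, tolerance = 1e-4)
  expect_equal(propagate_deterministic(ss_bi, 20, gam, t_star), 500,
               tolerance = 1e-9)
  expect_equal(crossing_time(ss_bi, 500, 20, gam), t_star,
               tolerance = 1e-12)
})

test_that("propagation composes exactly over subdivided intervals", {
  set.seed(11)
  for (i in 1:20) {
    n0 <- runif(1, 0, 6000)
    s <- runif(1, 0, 2000)
    g <- runif(1, 0.05, 1)
    t1 <- runif(1, 0, 10)
    t2 <- runif(1, 0, 10)
    expect_equal(
      propagate_deterministic(propagate_deterministic(n0, s, g, t1),
                              s, g, t2),
      propagate_deterministic(n0, s, g, t1 + t2),
      tolerance = 1e-13)
  }
})

test_that("steady-state levels separate the three expression regimes", {
  expect_equal(steady_state(2000, gam), 5770.780, tolerance = 1e-6)
  expect_equal(steady_state(0, gam), 0)
  expect_equal(steady_state(20, gam), 57.7078, tolerance = 1e-5)
  # monoallelic vs biallelic differ by (2 s_on)/(s_on + s_off)
  expect_equal(steady_state(2000, gam) / steady_state(1010, gam),
               2000 / 1010, tolerance = 1e-12)
  expect_equal(2000 / 1010, 1.980, tolerance = 1e-3)
  # silent cells sit two orders of magnitude below expressing ones
  expect_equal(steady_state(2000, gam) / steady_state(20, gam), 100)
})

test_that("total protein sums the allele-attributed pools", {
  expect_equal(total_nanog(list(n1 = 0, n2 = 0)), 0)
  expect_equal(total_nanog(list(n1 = 2914.2, n2 = 57.7)), 2971.9)
  # mean over expressing cells at the 1:4 biallelic:monoallelic ratio
  m <- 0.2 * steady_state(2000, gam) + 0.8 * steady_state(1010, gam)
  expect_equal(m, 3485.55, tolerance = 1e-5)
  snap <- data.frame(n1 = c(1, 2), n2 = c(10, 20))
  expect_equal(total_nanog(snap), c(11, 22))
})

test_that("noise-free SDE limit reproduces the closed form", {
  n0 <- 4000
  ref <- propagate_deterministic(n0, 1010, gam, 5)
  got <- propagate_sde(n0, 1010, gam, eta = 0, t = 5, dt = 0.01)
  expect_lt(abs(got - ref) / ref, 0.001)
})

test_that("SDE ensemble keeps the deterministic mean and eta orders the spread", {
  set.seed(21)
  ss <- steady_state(1010, gam)
  paths <- propagate_sde(rep(ss, 1e4), 1010, gam, eta = 0.2, t = 5,
                         dt = 0.01)
  expect_lt(abs(mean(paths) - ss) / ss, 0.02)
  cvs <- vapply(c(0.05, 0.1, 0.2), function(e) {
    p <- propagate_sde(rep(ss, 4000), 1010, gam, eta = e, t = 5, dt = 0.01)
    coefficient_of_variation(p)
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("production-noise model and shortened steps are accepted", {
  set.seed(3)
  p <- propagate_sde(100, 1010, gam, eta = 0.2, t = 0.003, dt = 0.01,
                     noise_model = "production")
  expect_true(is.finite(p) && p >= 0)
})
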