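hand_snapshot <- function() {
  data.frame(type = c(1, 1, 2, 2, 2, 3, 4, 4, 4, 4),
             n1 = c(2900, 3100, 2800, 2850, 2950, 30, 20, 25, 700, 40),
             n2 = c(2850, 3050, 25, 35, 30, 2900, 25, 30, 20, 35))
}

test_that("composition fractions agree with direct counting", {
  snap <- hand_snapshot()
  expect_equal(composition_fractions(snap), c(0.2, 0.3, 0.1, 0.4))
  expect_equal(composition_fractions(data.frame(type = rep(1, 5))),
               c(1, 0, 0, 0))
  expect_error(composition_fractions(data.frame(type = integer(0))),
               "empty")
})

test_that("positive fraction gates on total protein", {
  snap <- hand_snapshot()
  snap$n_total <- snap$n1 + snap$n2
  expect_equal(nanog_positive_fraction(snap, 500), 0.7)
  expect_equal(nanog_positive_fraction(snap, 1e-6), 1.0)
  expect_error(nanog_positive_fraction(snap, -1), "threshold")
  # ordering of rows is irrelevant
  expect_equal(nanog_positive_fraction(snap[sample(nrow(snap)), ], 500),
               0.7)
})

test_that("CV is the population standard deviation over the mean", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 0.5)
  expect_error(coefficient_of_variation(c(-2, 1)), "mean")
})

test_that("pearson correlation matches a hand-rolled covariance oracle", {
  x <- 1:50
  expect_equal(pearson_correlation(x, 2 * x + 1), 1.0)
  expect_equal(pearson_correlation(x, -x), -1.0)
  set.seed(2)
  a <- rnorm(100)
  b <- 0.5 * a + rnorm(100)
  num <- mean(a * b) - mean(a) * mean(b)
  den <- sqrt(mean(a^2) - mean(a)^2) * sqrt(mean(b^2) - mean(b)^2)
  expect_equal(pearson_correlation(a, b), num / den, tolerance = 1e-12)
  expect_error(pearson_correlation(a, rep(1, 100)), "variance")
  expect_error(pearson_correlation(a, b[1:10]), "length")
})

test_that("peak counting resolves well-separated mixture components", {
  set.seed(23)
  three <- c(rnorm(500, 50, 5), rnorm(500, 2900, 200), rnorm(500, 5800, 300))
  three <- pmax(three, 0)
  expect_equal(as.integer(histogram_peaks(three)), 3L)
  one <- rnorm(20000, 3000, 300)
  expect_equal(as.integer(histogram_peaks(one)), 1L)
  expect_error(histogram_peaks(1:50), "100")
})

test_that("2-D mode counting finds the vertices of a synthetic square", {
  set.seed(24)
  corner <- function(mx, my, n = 400)
    cbind(pmax(rnorm(n, mx, 0.12 * mx + 5), 0),
          pmax(rnorm(n, my, 0.12 * my + 5), 0))
  pts <- rbind(corner(30, 30), corner(30, 2900), corner(2900, 30),
               corner(2900, 2900))
  pk <- histogram_peaks_2d(pts[, 1], pts[, 2])
  expect_equal(as.integer(pk), 4L)
  # a single blob has one mode
  blob <- corner(500, 500, 1000)
  expect_equal(as.integer(histogram_peaks_2d(blob[, 1], blob[, 2])), 1L)
})

test_that("crossing times invert the closed-form trajectory", {
  gam <- log(2) / 2
  # silent-entry depletion and activation build-up, frozen from the
  # closed-form inversion
  expect_equal(crossing_time(5770.78, 2 * 57.7078, 20, gam), 13.2587,
               tolerance = 1e-4)
  expect_equal(crossing_time(2914.244, 2 * 57.7078, 20, gam), 11.2587,
               tolerance = 1e-4)
  expect_equal(crossing_time(57.7078, 0.8 * 2914.244, 1010, gam), 4.5861,
               tolerance = 1e-4)
  # within a 10% band of the silent level: the reported 15-20 h window
  t10 <- crossing_time(5770.78, 1.1 * 57.7078, 20, gam)
  expect_gt(t10, 15)
  expect_lt(t10, 20)
  # already there, or unreachable
  expect_equal(crossing_time(2914.244, 2914.244, 1010, gam), 0)
  expect_equal(crossing_time(100, 100, 1010, gam), 0)
  expect_equal(crossing_time(5770.78, 10, 20, gam), Inf)
})

test_that("depletion lag exceeds build-up lag whenever expression dominates leak", {
  st <- switching_timing()
  expect_equal(st$depletion_from_monoallelic_h, 11.2587, tolerance = 1e-4)
  expect_equal(st$buildup_to_monoallelic_h, 4.5861, tolerance = 1e-4)
  set.seed(31)
  for (i in 1:20) {
    pp <- expression_params(s_on = runif(1, 200, 3000),
                            s_off = runif(1, 0, 10),
                            half_life = runif(1, 0.5, 6))
    st <- switching_timing(pp)
    expect_gt(st$depletion_from_biallelic_h, st$buildup_to_monoallelic_h)
    expect_gt(st$depletion_from_monoallelic_h,
              st$buildup_to_monoallelic_h)
  }
})
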