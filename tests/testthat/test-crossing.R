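# Threshold-crossing framework: hazard, survival and crossing probabilities.

test_that("expansion threshold takes the clinical max of absolute and relative rules", {
  t1 <- expansion_threshold(10)
  expect_equal(t1$c, 22.5)
  expect_identical(t1$branch, "absolute")
  t2 <- expansion_threshold(50)
  expect_equal(t2$c, 66.5)
  expect_identical(t2$branch, "relative")
  # crossover where both rules agree: v0 + 12.5 = 1.33 v0  =>  v0 = 12.5/0.33
  v_star <- 12.5 / 0.33
  t3 <- expansion_threshold(v_star)
  expect_equal(t3$c, v_star + 12.5, tolerance = 1e-12)
  expect_equal(t3$c, 1.33 * v_star, tolerance = 1e-12)
  expect_error(expansion_threshold(-1), "non-negative")
  expect_error(expansion_threshold(NaN), "non-negative")
  expect_error(expansion_threshold(Inf), "non-negative")
})

test_that("instantaneous exceedance is the Gaussian upper tail", {
  expect_equal(instantaneous_exceedance(5, 1, 5), 0.5)
  expect_equal(instantaneous_exceedance(-10, 1e-10, 0), 0)
  expect_equal(instantaneous_exceedance(0, 1, 1.959964), 0.025, tolerance = 1e-7)
  # quadrature oracle for the tail integral on a few cases
  for (ca in list(c(0, 1, 0.7), c(2, 4, 3.1), c(-1, 0.25, 0.2))) {
    quad <- stats::integrate(function(v) dnorm(v, ca[1], sqrt(ca[2])),
                             ca[3], Inf)$value
    expect_equal(instantaneous_exceedance(ca[1], ca[2], ca[3]), quad,
                 tolerance = 1e-8)
  }
  expect_error(instantaneous_exceedance(0, 0, 1), "positive")
  expect_error(instantaneous_exceedance(0, -1, 1), "positive")
  set.seed(1)
  b <- instantaneous_exceedance(rnorm(100, sd = 10), rexp(100) + 0.01,
                                rnorm(100, sd = 10))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("crossing probability matches the constant-hazard closed form", {
  p0 <- const_hazard_process(1e-12, horizon = 10, n_points = 100)
  expect_lt(crossing_probability(p0, 30)$probability, 1e-10)
  p1 <- const_hazard_process(0.05, horizon = 10, n_points = 1000)
  expect_equal(crossing_probability(p1, 30)$probability, 1 - exp(-0.5),
               tolerance = 1e-10)
  p2 <- const_hazard_process(0.5, horizon = 2, n_points = 200)
  expect_equal(crossing_probability(p2, 30)$probability, 1 - exp(-1),
               tolerance = 1e-10)
  cr <- crossing_probability(p1, 30)
  expect_equal(cr$probability, -expm1(-cr$cumulative_hazard))
  expect_true(all(cr$hazard_path >= 0 & cr$hazard_path <= 1))
})

test_that("survival is the exact complement of crossing", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    g <- time_grid(horizon = runif(1, 1, 48), n_points = n)
    pr <- volume_process(g, mean = rnorm(n, 20, 10), variance = rexp(n, 1 / 9) + 0.01)
    th <- expansion_threshold(runif(1, 0, 40))
    expect_equal(crossing_probability(pr, th)$probability +
                   survival_probability(pr, th), 1, tolerance = 1e-12)
  }
  p1 <- const_hazard_process(0.05, horizon = 10, n_points = 500)
  expect_equal(survival_probability(p1, 30), exp(-0.5), tolerance = 1e-10)
  expect_equal(survival_probability(const_hazard_process(1e-13, 10, 50), 30), 1,
               tolerance = 1e-10)
})

test_that("crossing probability is monotone in horizon, threshold and mean", {
  set.seed(42)
  base_mean <- 20 + cumsum(rnorm(100, 0.2, 0.5))
  base_var <- rep(9, 100)
  p_of <- function(n_keep, thr, shift = 0) {
    g <- time_grid(horizon = n_keep, n_points = n_keep)
    crossing_probability(
      volume_process(g, base_mean[seq_len(n_keep)] + shift, base_var[seq_len(n_keep)]),
      thr)$probability
  }
  horizons <- c(10, 25, 50, 100)
  ph <- vapply(horizons, p_of, numeric(1), thr = 35)
  expect_true(all(diff(ph) >= 0))
  thresholds <- c(25, 30, 35, 45)
  pt <- vapply(thresholds, function(th) p_of(100, th), numeric(1))
  expect_true(all(diff(pt) <= 0))
  shifts <- c(-5, 0, 5, 10)
  pm <- vapply(shifts, function(s) p_of(100, 35, s), numeric(1))
  expect_true(all(diff(pm) >= 0))
})

test_that("discretization refinement converges below 1e-4 for smooth hazards", {
  p_at <- function(k, rule = "left") {
    g <- time_grid(horizon = 24, n_points = k)
    mu <- 20 + 4 * (1 - exp(-g$points / 10))
    crossing_probability(volume_process(g, mu, rep(4, k)), 30, rule = rule)$probability
  }
  expect_lt(abs(p_at(1000) - p_at(500)), 1e-4)
  # trapezoidal rule agrees with the left-endpoint rule in the limit
  expect_lt(abs(p_at(1000, "trapezoid") - p_at(1000)), 1e-3)
})

test_that("Monte Carlo oracle agrees with the analytic probability", {
  p0 <- const_hazard_process(1e-14, horizon = 10, n_points = 50)
  mc0 <- monte_carlo_crossing(p0, 30, n_paths = 500, seed = 3)
  expect_identical(mc0$estimate, 0)

  p1 <- const_hazard_process(0.05, horizon = 10, n_points = 100)
  mc1 <- monte_carlo_crossing(p1, 30, n_paths = 20000, seed = 11)
  # the discrete-interval product is the MC estimand
  q <- instantaneous_exceedance(p1$mean, p1$variance, 30) * p1$grid$step
  exact <- 1 - prod(1 - q)
  expect_lt(abs(mc1$estimate - exact), 3 * mc1$std_error + 1e-12)
  expect_lt(abs(mc1$estimate - (1 - exp(-0.5))), 4 * mc1$std_error + 0.01)

  # reproducibility and the refine-grid guard
  mc1b <- monte_carlo_crossing(p1, 30, n_paths = 20000, seed = 11)
  expect_identical(mc1$estimate, mc1b$estimate)
  coarse <- const_hazard_process(0.5, horizon = 12, n_points = 3) # beta*dt = 2
  expect_error(monte_carlo_crossing(coarse, 30, n_paths = 200, seed = 1),
               "refine")
  expect_error(monte_carlo_crossing(p1, 30, n_paths = 10, seed = 1), "100")
})

test_that("Monte Carlo estimate converges to the analytic value as the grid refines", {
  for (k in c(10, 100, 1000)) {
    p <- const_hazard_process(0.05, horizon = 10, n_points = k)
    mc <- monte_carlo_crossing(p, 30, n_paths = 40000, seed = 5)
    ana <- crossing_probability(p, 30)$probability
    # discrete product differs from exp() by O(dt); both shrink with k
    expect_lt(abs(mc$estimate - ana), 3 * mc$std_error + 0.3 / k)
  }
})

test_that("volume process validates inputs and round-trips through CSV + JSON", {
  g <- time_grid(horizon = 6, n_points = 6)
  expect_error(volume_process(g, mean = rep(0, 6), variance = rep(0, 6)), "1e-12")
  expect_error(volume_process(g, mean = rep(NA_real_, 6), variance = rep(1, 6)),
               "finite")
  expect_error(volume_process(g, mean = 1:5, variance = rep(1, 5)), "length")
  expect_error(time_grid(horizon = 0, n_points = 5))
  expect_error(time_grid(horizon = 5, n_points = 0.5))

  pr <- volume_process(g, mean = rnorm(6, 20), variance = rexp(6) + 0.5)
  csv <- tempfile(fileext = ".csv")
  write_volume_process(pr, csv)
  pr2 <- read_volume_process(csv)
  expect_equal(pr2$mean, pr$mean)
  expect_equal(pr2$variance, pr$variance)
  expect_equal(pr2$grid$points, pr$grid$points)
})
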