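test_that("window fit recovers (alpha, pmax, re) exactly on noiseless data", {
  set.seed(31)
  par <- stats::runif(120, 20, 1800)
  rec <- records_from(120, par = par)
  rec$nee <- 0.12 - light_response_gross(par, 0.003, 0.7)
  fit <- fit_light_window(rec)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 0.003, tolerance = 1e-6)
  expect_equal(fit$pmax, 0.7, tolerance = 1e-6)
  expect_equal(fit$re, 0.12, tolerance = 1e-6)
  expect_equal(fit$n_obs, 120L)
  # fitted-curve limits: slope alpha at PAR = 0, asymptote pmax
  h <- 1e-6
  expect_equal(light_response_gross(h, fit$alpha, fit$pmax) / h, fit$alpha,
               tolerance = 1e-4)
  expect_equal(light_response_gross(1e9, fit$alpha, fit$pmax), fit$pmax,
               tolerance = 1e-4)
})

test_that("degenerate or sparse window designs are flagged", {
  rec <- records_from(60, par = 800)       # all PAR equal: rank-deficient
  rec$nee <- -0.3
  expect_false(fit_light_window(rec)$converged)
  small <- records_from(10, par = stats::runif(10, 100, 900))
  small$nee <- -0.2
  expect_false(fit_light_window(small)$converged)
})

test_that("every year is partitioned into exactly 73 calendar windows", {
  for (y in c(2011, 2012)) {             # common and leap year
    w <- year_windows(y)
    expect_equal(nrow(w), 73L)
    expect_equal(w$window_start[1], as.Date(sprintf("%d-01-01", y)))
    expect_equal(w$window_end[73], as.Date(sprintf("%d-12-31", y)))
    # disjoint and exhaustive over the day index
    days <- unlist(mapply(function(a, b) seq(a, b, by = "day"),
                          w$window_start, w$window_end, SIMPLIFY = FALSE))
    year_days <- seq(as.Date(sprintf("%d-01-01", y)),
                     as.Date(sprintf("%d-12-31", y)), by = "day")
    expect_equal(sort(as.Date(days, origin = "1970-01-01")), year_days)
    expect_equal(as.integer(table(window_index(year_days))[72:73]),
                 c(5L, if (y == 2012) 6L else 5L))
  }
  expect_equal(year_windows(2011)$window_start[73], as.Date("2011-12-27"))
  expect_equal(year_windows(2012)$window_start[73], as.Date("2012-12-26"))
})

test_that("a full synthetic year yields 73 window fits tracking the truth", {
  yr <- noiseless_year(seed = 21)
  fits <- fit_light_year(yr$records)
  expect_equal(nrow(fits), 73L)
  expect_true(all(fits$window == 1:73))
  conv <- fits$converged
  expect_gt(sum(conv), 60)
  # fitted window parameters track the generating trajectories.  Pmax is
  # sharply identified; alpha inherits a bias from within-window respiration
  # variation (the window model holds RE constant while true RE follows Ts),
  # so only a loose positive association can be guaranteed for it.
  truth_by_window <- aggregate(yr$truth$daily[c("alpha", "pmax")],
                               by = list(window = window_index(yr$truth$daily$date)),
                               mean)
  expect_gt(stats::cor(fits$pmax[conv], truth_by_window$pmax[conv]), 0.95)
  expect_gt(stats::cor(fits$alpha[conv], truth_by_window$alpha[conv]), 0.3)
  expect_lt(stats::median(abs(fits$alpha[conv] - truth_by_window$alpha[conv]) /
                            truth_by_window$alpha[conv]), 0.10)
})

test_that("Gaussian smoothing conserves kernel mass and handles flagged windows", {
  expect_equal(smooth_gaussian(rep(3.3, 40), sigma = 2), rep(3.3, 40))
  # single spike spreads by the discrete Gaussian weights
  x <- c(rep(0, 10), 1, rep(0, 10))
  sm <- smooth_gaussian(x, sigma = 1)
  i <- seq_along(x)
  w <- exp(-((i - 11)^2) / 2)
  expected <- vapply(i, function(j) {
    wj <- exp(-((i - j)^2) / 2)
    sum(wj * x) / sum(wj)
  }, numeric(1))
  expect_equal(sm, expected, tolerance = 1e-12)
  expect_equal(which.max(sm), 11L)
  # excluded (non-converged) entries do not leak into the average
  y <- c(1, 1, 100, 1, 1)
  sm2 <- smooth_gaussian(y, sigma = 1, valid = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(sm2, rep(1, 5))
  # interior-dominated series: smoothed mean equals raw mean
  set.seed(8)
  z <- stats::rnorm(400)
  expect_equal(mean(smooth_gaussian(z, sigma = 1.5)), mean(z), tolerance = 1e-2)
  expect_error(smooth_gaussian(z, sigma = 0), "positive")
})
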