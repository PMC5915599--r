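test_that("tangent lag is exact on an analytic logistic curve", {
  k <- 0.05; t0 <- 200
  t <- seq(0, 400, 0.25)
  lr <- extract_lag(list(times = t, f_poly = 1 / (1 + exp(-k * (t - t0)))))
  expect_lt(abs(lr$t_lag_s - (t0 - 2 / k)), 0.5)
  expect_equal(lr$max_rate_per_s, k / 4, tolerance = 1e-3)
  # moderate smoothing must not bias the symmetric curve
  lr11 <- extract_lag(list(times = t, f_poly = 1 / (1 + exp(-k * (t - t0)))),
                      smooth_window = 11)
  expect_lt(abs(lr11$t_lag_s - (t0 - 2 / k)), 0.5)
})

test_that("a linear ramp from the origin has zero lag", {
  t <- seq(0, 100, 0.5)
  lr <- extract_lag(list(times = t, f_poly = t / 100))
  expect_equal(lr$t_lag_s, 0, tolerance = 1e-8)
})

test_that("degenerate curves are rejected", {
  t <- seq(0, 100, 1)
  expect_error(extract_lag(list(times = t, f_poly = rep(0, length(t)))),
               "insufficient")
  # rises then collapses below half its plateau
  expect_error(extract_lag(list(times = t, f_poly = exp(-(t - 20)^2 / 20))),
               "insufficient")
  expect_error(extract_lag(list(times = t, f_poly = t / 100),
                           smooth_window = 4), "odd")
})

test_that("without nucleators the polymerized fraction stays near zero", {
  pc <- simulate_bulk(vca_uM = 0, arp_uM = 0, cp_nM = 0, t_end = 300)
  expect_lt(max(pc$f_poly), 1e-6)
})

test_that("noisy curves are reproducible under a fixed seed", {
  a <- simulate_bulk(cp_nM = 20, t_end = 100, noise_sd = 0.02, seed = 5)
  b <- simulate_bulk(cp_nM = 20, t_end = 100, noise_sd = 0.02, seed = 5)
  expect_identical(a$f_poly, b$f_poly)
  d <- simulate_bulk(cp_nM = 20, t_end = 100, noise_sd = 0.02, seed = 6)
  expect_false(identical(a$f_poly, d$f_poly))
  expect_true(all(a$f_poly >= 0 & a$f_poly <= 1))
})

test_that("CP introduces a distinct delay before polymerization", {
  no_cp <- std_curve(0)
  cp20 <- std_curve(20)
  half_time <- function(pc) pc$times[which(pc$f_poly >= 0.5 * max(pc$f_poly))[1]]
  expect_gt(half_time(cp20), half_time(no_cp))
})

test_that("lag grows and peak rate falls across the CP sweep", {
  res <- vapply(c(20, 40, 80, 120), function(cp) {
    lr <- extract_lag(std_curve(cp))
    c(lr$t_lag_s, lr$max_rate_per_s)
  }, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("lag extraction is robust to observation noise", {
  ref <- extract_lag(std_curve(20))$t_lag_s
  base <- std_curve(20)
  lags <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- list(times = base$times,
                  f_poly = pmin(pmax(base$f_true +
                                       rnorm(length(base$times), sd = 0.01),
                                     0), 1))
    extract_lag(noisy, smooth_window = 21)$t_lag_s
  }, numeric(1))
  expect_true(all(abs(lags - ref) / ref < 0.10))
})
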