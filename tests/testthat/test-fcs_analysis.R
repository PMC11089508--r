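test_that("the 2D FCS model has the textbook anchors", {
  expect_equal(fcs_model(0, N = 5, T_D = 3.1e-3), 0.2)
  expect_equal(fcs_model(3.1e-3, N = 5, T_D = 3.1e-3), 0.1)
  expect_lt(fcs_model(10, N = 5, T_D = 3.1e-3), 1e-3)
})

test_that("white noise correlates to zero beyond lag zero", {
  set.seed(3)
  x <- rpois(5e4, 20)
  corr <- autocorrelate(x, sample_dt = 1e-4)
  # sampling error ~ 1/sqrt(n); all lags should hug zero
  expect_lt(max(abs(corr$G)), 0.01)
})

test_that("the correlator is deterministic and rejects degenerate traces", {
  set.seed(4)
  x <- rpois(2e4, 10)
  a <- autocorrelate(x, 1e-4)
  b <- autocorrelate(x, 1e-4)
  expect_identical(a, b)
  expect_error(autocorrelate(rep(5, 2e4), 1e-4), "constant")
  expect_error(autocorrelate(x[1:100], 1e-4), "1e4")
})

test_that("a noiseless model curve is inverted to 0.1%", {
  lags <- exp(seq(log(1e-4), log(0.3), length.out = 60))
  corr <- corr_trace(lags, fcs_model(lags, N = 5, T_D = 3.1e-3))
  fit <- fit_fcs(corr)
  expect_equal(fit$N, 5, tolerance = 1e-3)
  expect_equal(fit$T_D, 3.1e-3, tolerance = 1e-3)
  expect_true(fit$lag_span_ok)
})

test_that("5% correlation noise leaves transit-time bias under 3%", {
  lags <- exp(seq(log(1e-4), log(0.3), length.out = 60))
  clean <- fcs_model(lags, N = 5, T_D = 3.1e-3)
  T_Ds <- vapply(1:50, function(s) {
    g <- confineR:::with_seed(s, clean * (1 + rnorm(length(clean), 0, 0.05)))
    fit_fcs(corr_trace(lags, g))$T_D
  }, numeric(1))
  expect_lt(abs(mean(T_Ds) / 3.1e-3 - 1), 0.03)
})

test_that("all-zero correlations are rejected", {
  lags <- exp(seq(log(1e-4), log(0.1), length.out = 12))
  expect_error(fit_fcs(corr_trace(lags, rep(0, 12))), "zero")
})

test_that("transit times convert to D by w^2/(4 T_D)", {
  expect_equal(diffusion_from_transit(3.1233e-3, 0.191)$D, 2.92,
               tolerance = 1e-3)
  # doubling the waist at fixed transit time quadruples D
  r <- diffusion_from_transit(1e-3, 0.4)$D / diffusion_from_transit(1e-3, 0.2)$D
  expect_equal(r, 4)
  # uncertainty propagates in quadrature
  u <- diffusion_from_transit(3.1e-3, 0.191, T_D_sd = 3.1e-4, w_sd = 0.00742)
  expect_equal(u$D_sd / u$D, sqrt(0.1^2 + (2 * 0.00742 / 0.191)^2),
               tolerance = 1e-6)
})

test_that("waist calibration inverts the transit conversion", {
  w0 <- calibrate_waist(3.1233e-3, 2.92)$w
  expect_equal(diffusion_from_transit(3.1233e-3, w0)$D, 2.92,
               tolerance = 1e-9)
  expect_error(calibrate_waist(1e-3, 0), "> 0")
  # waist spread across repeated calibrations ~ sample SD of the ten
  T_cal <- confineR:::with_seed(9, 3.1e-3 * (1 + rnorm(10, 0, 0.03)))
  cal <- calibrate_waist(T_cal, 414)
  expect_equal(cal$w_sd, sd(sqrt(4 * 414 * T_cal)), tolerance = 1e-12)
})

test_that("acquisitions aggregate by averaging T_D, then converting", {
  mk <- function(T_D, N) structure(list(T_D = T_D, N = N), class = "fcs_fit")
  agg <- aggregate_acquisitions(list(mk(2e-3, 4), mk(4e-3, 6)), w = 0.191)
  expect_equal(agg$T_D, 3e-3)
  expect_equal(agg$N, 5)
  # D comes from the averaged T_D, not the averaged per-acquisition D
  expect_equal(agg$D, 0.191^2 / (4 * 3e-3))
  # permutation symmetry
  agg2 <- aggregate_acquisitions(list(mk(4e-3, 6), mk(2e-3, 4)), w = 0.191)
  expect_equal(agg2$D, agg$D)
  expect_error(aggregate_acquisitions(list()), "no fits")
  expect_error(aggregate_acquisitions(list(mk(1e-3, 2))), "at least 2")
})

test_that("correlation tables round-trip through CSV", {
  lags <- exp(seq(log(1e-4), log(0.1), length.out = 30))
  corr <- corr_trace(lags, fcs_model(lags, 3, 2e-3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corr_trace(corr, path)
  back <- read_corr_trace(path)
  expect_equal(back$G, corr$G, tolerance = 1e-8)
})

test_that("tracer round trip recovers the transit time and D", {
  # single 5 s acquisition in a free bilayer: correlate + fit recovers
  # T_D = w^2/(4D) within sampling error
  tr <- fcs_trace(D = 2.92, duration = 5, mean_N = 1, seed = 5,
                  box_halfwidth = 2.5)
  corr <- autocorrelate(tr$intensity, attr(tr, "sample_dt"))
  fit <- fit_fcs(corr)
  expect_equal(fit$T_D, 0.191^2 / (4 * 2.92), tolerance = 0.15)
  expect_equal(diffusion_from_transit(fit$T_D, 0.191)$D, 2.92,
               tolerance = 0.15)
})
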