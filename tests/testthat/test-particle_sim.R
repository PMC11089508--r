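test_that("zero diffusion leaves positions unchanged", {
  res <- brownian_evolve(x = c(0, 1), y = c(0, -1), mask = NULL,
                         D = 0, dt = 1e-3, n_steps = 100,
                         box_halfwidth = 5, seed = 1)
  expect_identical(res$x, c(0, 1))
  expect_identical(res$y, c(0, -1))
})

test_that("free-space MSD follows the Einstein relation", {
  n <- 1e4; D <- 2.92; t_end <- 1
  dt <- 1e-3
  res <- brownian_evolve(rep(0, n), rep(0, n), mask = NULL, D = D, dt = dt,
                         n_steps = round(t_end / dt), box_halfwidth = 50,
                         seed = 42)
  msd <- mean(res$x^2 + res$y^2)
  se <- sd(res$x^2 + res$y^2) / sqrt(n)
  expect_lt(abs(msd - 4 * D * t_end), 3 * se)
})

test_that("particles in a sealed box equilibrate to uniform occupancy", {
  # sealed square box: no escape, chi-squared test on a coarse grid
  n <- 4000
  pos <- sample_free_positions(n, NULL, c(-1, 1, -1, 1), seed = 3)
  res <- brownian_evolve(pos$x, pos$y, mask = NULL, D = 1, dt = 5e-4,
                         n_steps = 4000, box_halfwidth = 1, seed = 4)
  expect_true(all(abs(res$x) <= 1) && all(abs(res$y) <= 1))
  bins <- cut(res$x, seq(-1, 1, length.out = 5)):cut(res$y, seq(-1, 1, length.out = 5))
  counts <- table(bins)
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
})

test_that("reflecting obstacles exclude tracers from obstacle cells", {
  spec <- geometry_spec("four_pillars", R = 3, pillar_radius = 1)
  mask <- rasterize(spec, spacing = 0.1, domain_halfwidth = 5)
  pos <- sample_free_positions(3000, mask, c(-5, 5, -5, 5), seed = 8)
  res <- brownian_evolve(pos$x, pos$y, mask, D = 2.92, dt = 2e-4,
                         n_steps = 2000, seed = 9)
  ix <- floor((res$x - mask$origin[1]) / mask$spacing + 0.5) + 1
  iy <- floor((res$y - mask$origin[2]) / mask$spacing + 0.5) + 1
  inside <- ix >= 1 & ix <= nrow(mask$grid) & iy >= 1 & iy <= ncol(mask$grid)
  frac_in_obstacle <- mean(mask$grid[cbind(ix[inside], iy[inside])])
  expect_lt(frac_in_obstacle, 1e-3)
})

test_that("immobile emitters give a constant trace", {
  tr <- fcs_trace(D = 0, duration = 0.6, sample_dt = 5e-4, mean_N = 1,
                  brightness = 10, seed = 12, box_halfwidth = 2)
  expect_equal(diff(range(tr$intensity)), 0)
})

test_that("oversized trace requests are refused", {
  expect_error(fcs_trace(D = 1, duration = 1e6, sample_dt = 1e-6, seed = 1),
               "1e8")
})

test_that("escape times diverge as channels narrow", {
  means <- vapply(c(0.4, 0.1, 0.02), function(s)
    escape_times(s, n_channels = 1, R = 3, D = 2.92, n_particles = 300,
                 seed = 21)$mean, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("fully absorbing disk from the centre gives R^2/(4D)", {
  # classical mean first-passage time for an absorbing circle, start at
  # the centre: tau = R^2 / (4 D)
  R <- 3; D <- 2.92
  et <- escape_times(sigma = 0.999999, n_channels = 1, R = R, D = D,
                     n_particles = 3000, start = "center",
                     dt = 1e-5, seed = 31)
  expect_equal(et$n_censored, 0)
  expect_lt(abs(et$mean - R^2 / (4 * D)) / (R^2 / (4 * D)), 0.05)
})

test_that("independent seeds agree within combined standard errors", {
  a <- escape_times(0.1, 1, R = 3, D = 2.92, n_particles = 500, seed = 1)
  b <- escape_times(0.1, 1, R = 3, D = 2.92, n_particles = 500, seed = 2)
  expect_lt(abs(a$mean - b$mean), 3 * sqrt(a$se^2 + b$se^2))
})

test_that("censored particles are reported, not dropped", {
  et <- escape_times(0.01, 1, R = 3, D = 2.92, n_particles = 50,
                     max_time = 0.5, seed = 5)
  expect_equal(length(et$times), 50)
  expect_gt(et$n_censored, 0)
  expect_true(all(et$times[et$censored] == 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_escape_times(et, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 50)
  expect_equal(sum(d$censored), et$n_censored)
})
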