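test_that("a uniform field is a fixed point of the update", {
  mask <- rasterize(geometry_spec("none", R = 2), spacing = 0.2,
                    domain_halfwidth = 3)
  f <- new_field(mask, value = 0.7)
  g <- diffusion_step(f, mask, D = 1, dt = 0.005, n_steps = 50)
  expect_equal(max(abs(g$values - 0.7)), 0, tolerance = 1e-14)
})

test_that("unstable time steps are rejected", {
  mask <- rasterize(geometry_spec("none", R = 2), spacing = 0.1,
                    domain_halfwidth = 3)
  f <- new_field(mask)
  expect_error(diffusion_step(f, mask, D = 1, dt = 0.01), "unstable")
})

test_that("point-source evolution matches the 2D heat kernel", {
  spacing <- 0.1
  mask <- rasterize(geometry_spec("none", R = 2), spacing = spacing,
                    domain_halfwidth = 6)
  f <- new_field(mask, value = 0)
  n <- nrow(f$values)
  ic <- (n + 1) %/% 2
  f$values[ic, ic] <- 1 / spacing^2          # unit mass delta
  D <- 1; t_end <- 0.5
  dt <- 0.2 * spacing^2 / D
  nst <- round(t_end / dt)
  g <- diffusion_step(f, mask, D, dt, n_steps = nst)
  t_end <- nst * dt
  xs <- (seq_len(n) - ic) * spacing
  r2 <- outer(xs^2, xs^2, "+")
  kernel <- exp(-r2 / (4 * D * t_end)) / (4 * pi * D * t_end)
  l2 <- sqrt(sum((g$values - kernel)^2) / sum(kernel^2))
  expect_lt(l2, 0.01)
})

test_that("mass is conserved to machine precision through obstacles", {
  spec <- geometry_spec("four_pillars", R = 4, pillar_radius = 1.2)
  mask <- rasterize(spec, spacing = 0.1, domain_halfwidth = 6)
  proto <- frap_protocol(bleach_radius = 4, bleach_depth = 0.9,
                         record_times = seq(0.2, 6, by = 0.2))
  trace <- simulate_frap(mask, D = 2.92, proto)
  # relative drift per simulated second stays below 1e-10
  expect_lt(attr(trace, "mass_drift") / 6, 1e-10)
})

test_that("zero bleach depth yields a flat unit trace", {
  mask <- rasterize(geometry_spec("none", R = 3), spacing = 0.15,
                    domain_halfwidth = 6)
  proto <- frap_protocol(bleach_radius = 3, bleach_depth = 0,
                         record_times = seq(0.5, 4, by = 0.5))
  trace <- simulate_frap(mask, D = 2.92, proto)
  expect_equal(trace$intensity_norm, rep(1, nrow(trace)), tolerance = 1e-12)
})

test_that("free-space recovery fits the Soumpasis model with tiny residuals", {
  sim <- small_free_frap(D = 2.92, R = 4, t_max = 12)
  fit <- fit_recovery(sim$trace)
  amp <- diff(range(sim$trace$intensity_norm))
  expect_lt(fit$residual_rms / amp, 1e-3)
  expect_equal(fit$D, 2.92, tolerance = 0.05)
})

test_that("bleach disks overlapping the domain edge are rejected", {
  mask <- rasterize(geometry_spec("none", R = 3), spacing = 0.2,
                    domain_halfwidth = 4)
  proto <- frap_protocol(bleach_radius = 4.5,
                         record_times = seq(0.5, 2, by = 0.5))
  expect_error(simulate_frap(mask, 2.92, proto), "domain edge")
})

test_that("a nearly sealed region plateaus below full recovery", {
  R <- 4
  spec <- geometry_spec("one_channel", R = R, arclength = 0.45)
  mask <- rasterize(spec, spacing = 0.1, domain_halfwidth = 8)
  proto <- frap_protocol(bleach_radius = R, bleach_depth = 0.9,
                         record_times = seq(0.5, 15, by = 0.5))
  trace <- simulate_frap(mask, 2.92, proto)
  # free recovery would reach ~0.9 by t = 15 s (T_free = 1.37 s);
  # the sealed region must retain most of its bleach deficit
  expect_lt(trace$intensity_norm[nrow(trace)], 0.55)
  expect_gt(trace$intensity_norm[nrow(trace)], trace$intensity_norm[1])
})

test_that("effective diffusion is the identity without obstacles", {
  sim <- small_free_frap(D = 2.92, R = 4, t_max = 12)
  res <- effective_diffusion(sim$mask, 2.92, sim$proto)
  expect_equal(res$D_eff / 2.92, 1, tolerance = 0.05)
})

test_that("halving spacing and dt changes D_eff by under 2%", {
  R <- 3
  spec <- geometry_spec("four_channels", R = R,
                        arclength = 2 * pi * R * 0.3 / 4)
  proto <- frap_protocol(bleach_radius = R, bleach_depth = 0.9,
                         record_times = seq(0.25, 25, by = 0.25))
  coarse <- effective_diffusion(rasterize(spec, 0.1, 2.5 * R), 2.92, proto)
  fine <- effective_diffusion(rasterize(spec, 0.05, 2.5 * R), 2.92, proto)
  expect_lt(abs(coarse$D_eff - fine$D_eff) / fine$D_eff, 0.02)
})

test_that("particle occupancy reproduces the PDE recovery curve", {
  R <- 4
  spec <- geometry_spec("one_channel", R = R, arclength = 0.3 * 2 * pi * R)
  mask <- rasterize(spec, spacing = 0.1, domain_halfwidth = 8)
  proto <- frap_protocol(bleach_radius = R, bleach_depth = 0.9,
                         record_times = seq(0.4, 8, by = 0.4))
  pde <- simulate_frap(mask, 2.92, proto)
  par <- particle_frap_occupancy(mask, 2.92, proto, n_particles = 1e4,
                                 seed = 77)
  expect_equal(nrow(par), nrow(pde))
  # Monte-Carlo error at 1e4 tracers: a few percent per time point
  expect_lt(mean(abs(par$intensity_norm - pde$intensity_norm)), 0.03)
})
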