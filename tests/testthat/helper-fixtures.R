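# Shared fixtures, generated in code at test time. Sizes are deliberately
# small: a bleach radius of a few microns keeps solver grids and particle
# counts desk-scale while exercising exactly the same code paths as the
# full-size protocol.

# noiseless Soumpasis forward curve (single species)
synth_recovery <- function(T = 12.8478, R = 12.25, I0 = 0.1, A = 0.9,
                           times = seq(0.25, 80, by = 0.25), alpha = 1,
                           noise_sd = 0, seed = NULL) {
  y <- confineR:::frap_model(times, I0, A, T, alpha)
  if (noise_sd > 0)
    y <- confineR:::with_seed(seed, y * (1 + rnorm(length(y), 0, noise_sd)))
  recovery_trace(times, y, bleach_radius = R)
}

# small free-space FRAP simulation (fast: ~1 s)
small_free_frap <- function(D = 2.92, R = 4, spacing = 0.1,
                            halfwidth_factor = 4,
                            t_max = 10, n_rec = 100) {
  mask <- frap_domain(geometry_spec("none", R = R), spacing = spacing,
                      halfwidth_factor = halfwidth_factor)
  proto <- frap_protocol(bleach_radius = R,
                         record_times = seq(t_max / n_rec, t_max,
                                            length.out = n_rec))
  list(mask = mask, proto = proto,
       trace = simulate_frap(mask, D, proto))
}
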