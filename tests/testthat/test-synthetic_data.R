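# dataset sizes here use a reduced radius so the solver grids stay small;
# the generator's protocol defaults (R = 12.25, D = 2.92, 10 x 5 s FCS)
# are exercised by the acceptance suite

test_that("zero noise reproduces the solver output exactly", {
  ds <- make_frap_dataset("one_channel", sigma_values = 0.3, R_b = 4,
                          spacing = 0.1, noise = noise_model(0),
                          seed = 1)
  tr <- ds$traces[[1]]
  spec <- sigma_sweep("one_channel", 0.3, R = 4)[[1]]
  mask <- frap_domain(spec, spacing = 0.1, halfwidth_factor = 2.5)
  t_free <- 16 / (4 * 2.92)
  proto <- frap_protocol(bleach_radius = 4,
                         record_times = seq(t_free / 40, 10 * t_free / 0.3,
                                            length.out = 200))
  direct <- simulate_frap(mask, 2.92, proto)
  expect_equal(tr$intensity_norm, direct$intensity_norm, tolerance = 1e-12)
})

test_that("datasets are deterministic under a fixed seed", {
  a <- make_frap_dataset("four_channels", sigma_values = c(0.2, 0.5),
                         R_b = 4, spacing = 0.1, seed = 7)
  b <- make_frap_dataset("four_channels", sigma_values = c(0.2, 0.5),
                         R_b = 4, spacing = 0.1, seed = 7)
  expect_identical(a, b)
  c2 <- make_frap_dataset("four_channels", sigma_values = c(0.2, 0.5),
                          R_b = 4, spacing = 0.1, seed = 8)
  expect_false(identical(a$traces, c2$traces))
})

test_that("the truth table matches a pipeline refit of noiseless traces", {
  ds <- make_frap_dataset("four_channels", sigma_values = c(0.3, 0.6),
                          R_b = 4, spacing = 0.1, noise = noise_model(0),
                          seed = 2)
  for (i in seq_len(nrow(ds$truth))) {
    fit <- fit_recovery(ds$traces[[ds$truth$name[i]]])
    expect_equal(fit$D, ds$truth$D_eff_noiseless[i], tolerance = 0.05)
  }
  # noiseless effective D never exceeds the local D
  expect_true(all(ds$truth$D_eff_noiseless <= ds$truth$D_true * 1.05))
})

test_that("dataset export writes the documented directory layout", {
  out <- withr::local_tempdir()
  make_frap_dataset("one_channel", sigma_values = 0.4, R_b = 4,
                    spacing = 0.1, seed = 3, out_dir = out)
  expect_true(file.exists(file.path(out, "truth.csv")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  expect_true(file.exists(file.path(out, "MANIFEST.json")))
  expect_length(list.files(file.path(out, "traces"), pattern = "\\.csv$"), 1)
  manifest <- jsonlite::read_json(file.path(out, "MANIFEST.json"))
  expect_equal(manifest$seed, 3)
})

test_that("FCS truth table tracks the waist scaling", {
  ds <- make_fcs_dataset("none", D_true = 2.92, w = 0.191, n_acq = 2L,
                         duration = 0.8, seed = 4)
  expect_equal(ds$truth$T_D_expected, 0.191^2 / (4 * 2.92))
  ds2 <- make_fcs_dataset("none", D_true = 2.92, w = 0.0955, n_acq = 2L,
                          duration = 0.8, seed = 4)
  expect_equal(ds2$truth$T_D_expected / ds$truth$T_D_expected, 0.25,
               tolerance = 1e-9)
})

test_that("FCS dataset aggregates back to the generating D", {
  ds <- make_fcs_dataset("none", D_true = 2.92, n_acq = 4L, duration = 3,
                         seed = 5)
  agg <- recover_fcs_diffusion(ds)
  expect_equal(agg$D, 2.92, tolerance = 0.15)
})

test_that("the fixture suite regenerates the shipped files", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_suite(dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 4)
  # shipped copies under inst/extdata are byte-identical regenerations
  shipped <- system.file("extdata", "frap_free.csv", package = "confineR")
  if (nzchar(shipped)) {
    expect_identical(readLines(file.path(dir, "frap_free.csv")),
                     readLines(shipped))
  }
  tr <- read_recovery_trace(file.path(dir, "frap_one_channel_sigma0.1.csv"))
  expect_s3_class(tr, "recovery_trace")
  expect_gt(nrow(tr), 50)
})
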