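test_that("unobstructed fraction follows n*l/(2*pi*R)", {
  expect_equal(unobstructed_fraction(geometry_spec("none")), 1.0)
  # formula forces sigma = 1 when the single channel spans the circumference
  full <- geometry_spec("one_channel", R = 12.25,
                        arclength = 2 * pi * 12.25)
  expect_equal(unobstructed_fraction(full), 1.0)
  # hand arithmetic: 4 * 2.4053 / (2 * pi * 12.25)
  spec <- geometry_spec("four_channels", R = 12.25, arclength = 2.4053)
  expect_equal(unobstructed_fraction(spec), 0.125, tolerance = 1e-4)
})

test_that("channels exceeding the circumference are rejected", {
  expect_error(geometry_spec("four_channels", R = 2, arclength = 4),
               "circumference")
  expect_error(geometry_spec("four_pillars", R = 5, pillar_radius = 4),
               "overlap")
})

test_that("sigma sweep inverts the unobstructed fraction", {
  sig <- c(0.05, 0.125, 0.3, 0.6, 0.9)
  for (fam in c("one_channel", "four_channels")) {
    specs <- sigma_sweep(fam, sig, R = 12.25)
    got <- vapply(specs, unobstructed_fraction, numeric(1))
    expect_equal(got, sig, tolerance = 1e-9)
  }
  specs <- sigma_sweep("four_pillars", sig, R = 12.25)
  got <- vapply(specs, unobstructed_fraction, numeric(1))
  expect_equal(got, sig, tolerance = 1e-4)
  # spec with sigma = 0.125 at the fabricated radius has the printed arclength
  sp <- sigma_sweep("four_channels", 0.125, R = 12.25)[[1]]
  expect_equal(sp$arclength, 2.4053, tolerance = 1e-4)
  # sigma = 1 degenerates to the obstacle-free family
  expect_identical(sigma_sweep("one_channel", 1)[[1]]$family, "none")
  # pillar geometries cannot reach sigma -> 0 (pillars would overlap)
  expect_error(sigma_sweep("four_pillars", 1e-6), "overlap")
})

test_that("rasterized obstacle area converges to the analytic area", {
  spec <- geometry_spec("four_pillars", R = 12.25, pillar_radius = 2)
  m <- rasterize(spec, spacing = 0.05, domain_halfwidth = 16)
  expect_lt(abs(mask_area(m) - 4 * pi * 4) / (4 * pi * 4), 0.02)

  # annular channel wall: analytic area of the annulus sector complement
  spec2 <- geometry_spec("one_channel", R = 6, arclength = 1.2,
                         wall_thickness = 1)
  m2 <- rasterize(spec2, spacing = 0.05, domain_halfwidth = 9)
  frac_wall <- 1 - 1.2 / (2 * pi * 6)
  area2 <- frac_wall * pi * (7^2 - 6^2)
  expect_lt(abs(mask_area(m2) - area2) / area2, 0.02)

  # obstacle-free family rasterizes to an all-open mask
  expect_equal(sum(rasterize(geometry_spec("none", R = 5), 0.2, 8)$grid), 0)
})

test_that("narrow channels close up to the full ring as l -> 0", {
  R <- 6; l <- 0.21
  spec <- geometry_spec("one_channel", R = R, arclength = l)
  m <- rasterize(spec, spacing = 0.05, domain_halfwidth = 9)
  # open fraction of the annulus matches l/(2*pi*R) within ~a cell of arc
  frac_open <- 1 - mask_area(m) / (pi * (7^2 - 6^2))
  expect_lt(abs(frac_open - l / (2 * pi * R)), 2 * 0.05 / (2 * pi * R))
})

test_that("square-symmetric families are invariant under 90-degree rotation", {
  for (fam in c("four_channels", "four_pillars")) {
    spec <- sigma_sweep(fam, 0.3, R = 5)[[1]]
    g <- rasterize(spec, spacing = 0.1, domain_halfwidth = 7)$grid
    rot <- t(g[nrow(g):1, ])                 # 90-degree rotation
    expect_lt(mean(rot != g), 0.002)         # cell-centre discretization only
  }
})

test_that("too-coarse rasterization is rejected", {
  spec <- geometry_spec("four_channels", R = 12.25, arclength = 0.5)
  expect_error(rasterize(spec, spacing = 0.3, domain_halfwidth = 16),
               "too coarse")
})

test_that("geometry config round-trips through YAML", {
  spec <- geometry_spec("four_channels", R = 12.25, arclength = 2.4053,
                        wall_thickness = 0.8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_geometry_config(spec, path)
  back <- read_geometry_config(path)
  expect_equal(back$arclength, spec$arclength)
  expect_equal(unobstructed_fraction(back), unobstructed_fraction(spec))
})

test_that("mask text export carries header and grid", {
  m <- rasterize(geometry_spec("four_pillars", R = 4, pillar_radius = 1),
                 spacing = 0.1, domain_halfwidth = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mask(m, path)
  lines <- readLines(path)
  expect_match(lines[1], "spacing_um=0.1")
  expect_length(lines, 1 + ncol(m$grid))
  expect_equal(sum(as.integer(unlist(strsplit(lines[-1], "")))),
               sum(m$grid))
})
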