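# Brownian-dynamics oracle: point tracers with specular reflection off
# rasterized obstacle cell faces (shared geometric truth with the PDE) and
# off the outer box walls. Every stochastic entry point takes an explicit
# seed and leaves the caller's RNG untouched.

mask_args <- function(mask) {
  if (is.null(mask))
    return(list(m = NULL, ox = 0, oy = 0, dx = 1))
  stopifnot(inherits(mask, "obstacle_mask"))
  list(m = matrix(as.integer(mask$grid), nrow(mask$grid)),
       ox = mask$origin[1], oy = mask$origin[2], dx = mask$spacing)
}

mask_bounds <- function(mask, box_halfwidth, center = c(0, 0)) {
  if (!is.null(box_halfwidth))
    return(c(center[1] - box_halfwidth, center[1] + box_halfwidth,
             center[2] - box_halfwidth, center[2] + box_halfwidth))
  stopifnot(!is.null(mask))
  nx <- nrow(mask$grid); ny <- ncol(mask$grid)
  c(mask$origin[1] - mask$spacing / 2,
    mask$origin[1] + (nx - 0.5) * mask$spacing,
    mask$origin[2] - mask$spacing / 2,
    mask$origin[2] + (ny - 0.5) * mask$spacing)
}

# default Brownian time step: RMS displacement = half a grid cell, so
# boundary-crossing artifacts stay below discretization error
default_particle_dt <- function(spacing, D) (0.5 * spacing)^2 / (4 * D)

#' Sample particle positions uniformly over the free area
#'
#' Rejection-samples positions inside the box that avoid obstacle cells.
#'
#' @param n number of particles.
#' @param mask obstacle mask (or `NULL`).
#' @param bounds `c(xmin, xmax, ymin, ymax)` in μm.
#' @param seed RNG seed.
#' @return list with numeric vectors `x`, `y`.
#' @export
sample_free_positions <- function(n, mask, bounds, seed = NULL) {
  with_seed(seed, {
    ma <- mask_args(mask)
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
      k <- 2L * (n - length(xs)) + 16L
      x <- runif(k, bounds[1], bounds[2])
      y <- runif(k, bounds[3], bounds[4])
      if (!is.null(ma$m)) {
        ix <- floor((x - ma$ox) / ma$dx + 0.5)
        iy <- floor((y - ma$oy) / ma$dx + 0.5)
        inside <- ix >= 0 & ix < nrow(ma$m) & iy >= 0 & iy < ncol(ma$m)
        blocked <- logical(length(x))
        if (any(inside))
          blocked[inside] <- ma$m[cbind(ix[inside] + 1, iy[inside] + 1)] == 1
        x <- x[!blocked]; y <- y[!blocked]
      }
      xs <- c(xs, x); ys <- c(ys, y)
    }
    list(x = xs[seq_len(n)], y = ys[seq_len(n)])
  })
}

#' Evolve a Brownian ensemble among reflecting obstacles
#'
#' Gaussian displacements with per-axis variance `2 D dt`; moves ending in
#' an obstacle cell are specularly reflected off the crossed cell face, and
#' still-blocked moves (cell corners) are rejected in place and counted.
#'
#' @param x,y particle coordinates in μm.
#' @param mask obstacle mask, or `NULL` for free space.
#' @param D diffusion coefficient in μm²/s; `D = 0` returns the input.
#' @param dt time step in s; RMS step `sqrt(4 D dt)` must not exceed the
#'   grid spacing.
#' @param n_steps number of steps.
#' @param box_halfwidth reflecting outer box half-width in μm (default: the
#'   mask extent).
#' @param box_center box centre.
#' @param seed RNG seed.
#' @return list with `x`, `y`, `n_reject`.
#' @export
brownian_evolve <- function(x, y, mask = NULL, D, dt, n_steps,
                            box_halfwidth = NULL, box_center = c(0, 0),
                            seed = NULL) {
  stopifnot(length(x) == length(y))
  if (D == 0 || n_steps == 0)
    return(list(x = x, y = y, n_reject = 0))
  ma <- mask_args(mask)
  if (!is.null(mask) && sqrt(4 * D * dt) > mask$spacing * (1 + 1e-9))
    stop("step RMS sqrt(4 D dt) exceeds the grid spacing", call. = FALSE)
  b <- mask_bounds(mask, box_halfwidth, box_center)
  with_seed(seed,
    cpp_brownian_evolve(x, y, ma$m, ma$ox, ma$oy, ma$dx,
                        b[1], b[2], b[3], b[4], D, dt,
                        as.integer(n_steps)))
}

#' Simulate a binned FCS intensity trace
#'
#' Brownian tracers under a 2D Gaussian detection profile
#' `exp(-2 r^2 / w^2)` centred on the beam. The per-sample intensity is the
#' summed detection weight times `brightness` (counts per particle at beam
#' centre per sample); optional Poisson shot noise is applied per sample.
#'
#' @param mask obstacle mask, or `NULL` for a free bilayer patch.
#' @param D diffusion coefficient in μm²/s.
#' @param beam_center beam position `c(x, y)` in μm.
#' @param w beam waist (1/e² radius) in μm; default 0.191 μm.
#' @param duration trace duration in s; default one 5 s acquisition.
#' @param sample_dt sampling interval in s.
#' @param mean_N mean number of molecules in the detection area (sets the
#'   area density `mean_N / (pi w^2 / 2)`).
#' @param brightness expected counts per molecule per sample at beam
#'   centre.
#' @param shot_noise apply Poisson shot noise to each sample.
#' @param box_halfwidth simulation box half-width in μm (default: the mask
#'   extent, or `12 w` for free space — far enough that walls are unseen).
#' @param substeps Brownian steps per recorded sample.
#' @param seed RNG seed.
#' @return data.frame with columns `time_s`, `intensity`, plus attributes
#'   `sample_dt`, `n_particles`, `n_reject`.
#' @export
fcs_trace <- function(mask = NULL, D, beam_center = c(0, 0), w = 0.191,
                      duration = 5, sample_dt = 5e-5, mean_N = 1,
                      brightness = 5, shot_noise = FALSE,
                      box_halfwidth = NULL, substeps = 1L, seed = NULL) {
  stopifnot_scalar(D, "D")
  if (D < 0) stop("`D` must be >= 0", call. = FALSE)
  stopifnot_scalar(w, "w", positive = TRUE)
  n_samples <- floor(duration / sample_dt)
  if (n_samples * substeps > 1e8)
    stop("duration/sample_dt would exceed 1e8 steps; reduce the request",
         call. = FALSE)
  if (is.null(mask) && is.null(box_halfwidth)) box_halfwidth <- 12 * w
  b <- mask_bounds(mask, box_halfwidth, beam_center)
  if (min(b[2] - b[1], b[4] - b[3]) < 8 * w)
    stop("domain must be much larger than the beam waist", call. = FALSE)
  density <- mean_N / (pi * w^2 / 2)
  area <- (b[2] - b[1]) * (b[4] - b[3])
  ma <- mask_args(mask)
  with_seed(seed, {
    n_part <- max(rpois(1, density * area), 1L)
    pos <- sample_free_positions(n_part, mask, b)
    dt <- sample_dt / substeps
    res <- cpp_fcs_trace(pos$x, pos$y, ma$m, ma$ox, ma$oy, ma$dx,
                         b[1], b[2], b[3], b[4], D, dt,
                         as.integer(n_samples), as.integer(substeps),
                         beam_center[1], beam_center[2], w)
    I <- brightness * res$intensity
    if (shot_noise) I <- rpois(length(I), I)
    out <- data.frame(time_s = seq_len(n_samples) * sample_dt, intensity = I)
    attr(out, "sample_dt") <- sample_dt
    attr(out, "n_particles") <- n_part
    attr(out, "n_reject") <- res$n_reject
    out
  })
}

#' Bleach-disk occupancy of a Brownian ensemble (FRAP oracle)
#'
#' Initializes tracers as unbleached lipids (uniform over the free area,
#' thinned to `1 - bleach_depth` inside the bleach disk) and records the
#' tracer count inside the disk over time, normalized by the unbleached
#' expectation — the particle-level analogue of the PDE recovery trace.
#'
#' @param mask obstacle mask.
#' @param D diffusion coefficient in μm²/s.
#' @param protocol a [frap_protocol()].
#' @param n_particles tracers before thinning.
#' @param dt Brownian step in s (default [default_particle_dt()]).
#' @param seed RNG seed.
#' @return a data.frame with `time_s`, `intensity_norm` (plus attribute
#'   `n_tracked`).
#' @export
particle_frap_occupancy <- function(mask, D, protocol, n_particles = 1e4,
                                    dt = NULL, seed = NULL) {
  stopifnot(inherits(mask, "obstacle_mask"), inherits(protocol, "frap_protocol"))
  if (is.null(dt)) dt <- default_particle_dt(mask$spacing, D)
  b <- mask_bounds(mask, NULL)
  ma <- mask_args(mask)
  with_seed(seed, {
    pos <- sample_free_positions(n_particles, mask, b)
    r2 <- (pos$x - protocol$bleach_center[1])^2 +
          (pos$y - protocol$bleach_center[2])^2
    in_disk <- r2 <= protocol$bleach_radius^2
    # thin the disk population to emulate the bleach
    keep <- !in_disk | (runif(length(pos$x)) > protocol$bleach_depth)
    x <- pos$x[keep]; y <- pos$y[keep]
    # reference occupancy of an unbleached uniform ensemble
    f_eq <- mean(in_disk)
    steps <- pmax(as.integer(round(protocol$record_times / dt)), 1L)
    keep_s <- !duplicated(steps)
    res <- cpp_occupancy(x, y, ma$m, ma$ox, ma$oy, ma$dx,
                         b[1], b[2], b[3], b[4], D, dt, steps[keep_s],
                         protocol$bleach_center[1], protocol$bleach_center[2],
                         protocol$bleach_radius)
    # fraction of *surviving* tracers in disk, rescaled to the pre-bleach
    # level: occupancy * n_surviving / (n_total * f_eq)
    out <- data.frame(time_s = steps[keep_s] * dt,
                      intensity_norm = res$fraction * length(x) /
                        (n_particles * f_eq))
    attr(out, "n_tracked") <- length(x)
    out
  })
}

#' Narrow-escape first-passage times by Brownian dynamics
#'
#' Simulates tracers in the analytic disk of radius `R` whose boundary is
#' reflecting except for `n_channels` absorbing arcs of total angular
#' fraction `sigma`, and returns the per-particle time of first crossing of
#' an absorbing arc. Particles still inside at `max_time` are reported as
#' censored, never dropped.
#'
#' @param sigma unobstructed (absorbing) fraction in `(0, 1]`.
#' @param n_channels number of equally spaced absorbing arcs.
#' @param R disk radius in μm.
#' @param D diffusion coefficient in μm²/s.
#' @param n_particles number of first-passage samples.
#' @param start `"uniform"` over the disk or `"center"`.
#' @param dt Brownian step in s; default resolves the arc,
#'   `sqrt(4 D dt) = min(arc length, R) / 10`.
#' @param max_time censoring cap in s (default `60 R^2/D`).
#' @param seed RNG seed.
#' @return list with `times` (s), `censored` (logical), `mean`, `se`
#'   (computed over uncensored samples), `n_censored`.
#' @export
escape_times <- function(sigma, n_channels = 1L, R = 12.25, D = 2.92,
                         n_particles = 1000, start = c("uniform", "center"),
                         dt = NULL, max_time = 60 * R^2 / D, seed = NULL) {
  start <- match.arg(start)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (sigma > 1) stop("`sigma` must be <= 1", call. = FALSE)
  arc <- 2 * pi * R * sigma / n_channels
  if (is.null(dt)) dt <- (min(arc, R) / 10)^2 / (4 * D)
  with_seed(seed, {
    if (start == "center") {
      x0 <- rep(0, n_particles); y0 <- rep(0, n_particles)
    } else {
      rr <- R * sqrt(runif(n_particles))
      th <- runif(n_particles, 0, 2 * pi)
      x0 <- rr * cos(th); y0 <- rr * sin(th)
    }
    res <- cpp_escape_times(x0, y0, R, D, dt, sigma,
                            as.integer(n_channels), max_time)
    ok <- !res$censored
    list(times = res$time, censored = res$censored,
         mean = mean(res$time[ok]),
         se = sd(res$time[ok]) / sqrt(sum(ok)),
         n_censored = sum(!ok))
  })
}

#' Write escape-time samples as CSV
#'
#' One row per particle with columns `time_s`, `censored`.
#' @param esc an [escape_times()] result.
#' @param path output path.
#' @export
write_escape_times <- function(esc, path) {
  write.csv(data.frame(time_s = esc$times,
                       censored = as.integer(esc$censored)),
            path, row.names = FALSE)
  invisible(path)
}
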