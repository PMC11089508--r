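#' Confinement geometry specification
#'
#' Parametric description of one confinement pattern. Three families are
#' supported, mirroring the fabricated oxide structures: `"one_channel"` and
#' `"four_channels"` are arc walls on the circle of radius `R` interrupted by
#' `n_channels` escape channels of arclength `arclength` each;
#' `"four_pillars"` is four circular pillars in a square array, centred on
#' the square inscribed in the circle of radius `R`; `"none"` is an
#' obstacle-free reference. All lengths are in micrometres.
#'
#' For the pillar family the escape channels are not free parameters: they
#' are the four gap arcs left between the pillar silhouettes projected onto
#' the circle of radius `R`, so `n_channels` and `arclength` are derived from
#' `pillar_radius` (each pillar at distance `R` from the centre blocks an
#' angle `2*asin(pillar_radius/R)`).
#'
#' @param family one of `"none"`, `"one_channel"`, `"four_channels"`,
#'   `"four_pillars"`.
#' @param R confinement (bleach) radius in μm; default 12.25 μm.
#' @param arclength arclength of each escape channel in μm (channel
#'   families).
#' @param pillar_radius pillar radius in μm (`"four_pillars"` only).
#' @param wall_thickness radial thickness of the arc walls in μm.
#' @param center pattern centre `c(x, y)` in μm.
#' @return an object of class `"geometry_spec"`.
#' @seealso [unobstructed_fraction()], [rasterize()], [sigma_sweep()]
#' @examples
#' spec <- geometry_spec("four_channels", arclength = 2.4053)
#' unobstructed_fraction(spec)
#' @export
geometry_spec <- function(family = c("none", "one_channel", "four_channels",
                                     "four_pillars"),
                          R = 12.25, arclength = NULL, pillar_radius = NULL,
                          wall_thickness = 1.0, center = c(0, 0)) {
  family <- match.arg(family)
  stopifnot_scalar(R, "R", positive = TRUE)
  stopifnot_scalar(wall_thickness, "wall_thickness", positive = TRUE)
  if (length(center) != 2L || !is.numeric(center))
    stop("`center` must be a numeric length-2 vector", call. = FALSE)

  n_channels <- switch(family, none = 0L, one_channel = 1L,
                       four_channels = 4L, four_pillars = 4L)
  if (family == "four_pillars") {
    if (is.null(pillar_radius))
      stop("`pillar_radius` is required for family \"four_pillars\"",
           call. = FALSE)
    stopifnot_scalar(pillar_radius, "pillar_radius", positive = TRUE)
    if (pillar_radius >= R / sqrt(2))
      stop("pillars overlap: `pillar_radius` must be below R/sqrt(2) ",
           "(adjacent pillar centres are R*sqrt(2) apart)", call. = FALSE)
    # gap arcs between pillar silhouettes seen from the centre
    blocked <- 2 * asin(pillar_radius / R)      # angle blocked per pillar
    arclength <- R * (pi / 2 - blocked)
  } else if (family == "none") {
    arclength <- 2 * pi * R   # whole circumference open
    n_channels <- 1L
  } else {
    if (is.null(arclength))
      stop("`arclength` is required for channel families", call. = FALSE)
    stopifnot_scalar(arclength, "arclength", positive = TRUE)
  }
  if (n_channels * arclength > 2 * pi * R * (1 + 1e-12))
    stop("escape channels exceed the circumference: n * l > 2*pi*R",
         call. = FALSE)

  structure(list(family = family, R = R, n_channels = n_channels,
                 arclength = arclength,
                 pillar_radius = if (family == "four_pillars") pillar_radius,
                 wall_thickness = wall_thickness,
                 center = as.numeric(center)),
            class = "geometry_spec")
}

#' @export
print.geometry_spec <- function(x, ...) {
  cat(sprintf("<geometry_spec> family=%s R=%.4g um sigma=%.4g\n",
              x$family, x$R, unobstructed_fraction(x)))
  if (x$family == "four_pillars")
    cat(sprintf("  pillar_radius=%.4g um (4 pillars, square array)\n",
                x$pillar_radius))
  else if (x$family != "none")
    cat(sprintf("  %d channel(s) of arclength %.4g um, wall %.3g um\n",
                x$n_channels, x$arclength, x$wall_thickness))
  invisible(x)
}

#' Unobstructed fraction of a confinement pattern
#'
#' The fraction of the confinement circle's circumference open as escape
#' channels, `sigma = n * l / (2 * pi * R)`, where `n` is the number of
#' escape channels, `l` the arclength of each and `R` the radius of the
#' bleached region. `sigma = 1` for the obstacle-free family.
#'
#' @param spec a [geometry_spec()].
#' @return the unobstructed fraction, in `[0, 1]`.
#' @examples
#' unobstructed_fraction(geometry_spec("none"))  # 1
#' @export
unobstructed_fraction <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$family == "none") return(1.0)
  sigma <- spec$n_channels * spec$arclength / (2 * pi * spec$R)
  if (sigma > 1 + 1e-9)
    stop("invalid spec: n * l exceeds the circumference", call. = FALSE)
  min(sigma, 1.0)
}

# pillar radius giving unobstructed fraction sigma (four_pillars):
# sigma = 1 - (4/pi) * asin(a / R)  =>  a = R * sin(pi * (1 - sigma) / 4)
pillar_radius_for_sigma <- function(sigma, R) {
  R * sin(pi * (1 - sigma) / 4)
}

#' Sweep a geometry family over unobstructed fractions
#'
#' Builds one [geometry_spec()] per requested `sigma`. For channel families
#' the channel arclength is set to `l = 2*pi*R*sigma/n`; for the pillar
#' family the pillar radius is solved from the gap-arc definition of sigma
#' (closed form, exact). `sigma = 1` yields a degenerate, obstacle-free
#' spec (`family = "none"`).
#'
#' @param family `"one_channel"`, `"four_channels"` or `"four_pillars"`.
#' @param sigma_values unobstructed fractions, each in `(0, 1]`.
#' @param R confinement radius in μm.
#' @param wall_thickness wall thickness in μm for channel families.
#' @return a list of `geometry_spec` objects, one per sigma.
#' @examples
#' sigma_sweep("four_channels", c(0.125, 0.5))
#' @export
sigma_sweep <- function(family = c("one_channel", "four_channels",
                                   "four_pillars"),
                        sigma_values, R = 12.25, wall_thickness = 1.0) {
  family <- match.arg(family)
  if (any(sigma_values <= 0 | sigma_values > 1))
    stop("each sigma must lie in (0, 1]", call. = FALSE)
  lapply(sigma_values, function(s) {
    if (s == 1) return(geometry_spec("none", R = R))
    if (family == "four_pillars") {
      a <- pillar_radius_for_sigma(s, R)
      gap <- sqrt(2) * R - 2 * a      # clearance between adjacent pillars
      if (a >= R / sqrt(2) || gap < 1e-3 * R)
        stop(sprintf("sigma = %g is unreachable for four_pillars: pillars overlap or touch", s),
             call. = FALSE)
      geometry_spec("four_pillars", R = R, pillar_radius = a)
    } else {
      n <- if (family == "one_channel") 1L else 4L
      geometry_spec(family, R = R, arclength = 2 * pi * R * s / n,
                    wall_thickness = wall_thickness)
    }
  })
}

#' Rasterize a confinement geometry to a reflecting-obstacle mask
#'
#' Produces the boolean obstacle lattice used by both the finite-difference
#' diffusion solver and the Brownian-dynamics engine. A cell is an obstacle
#' iff its centre lies inside an obstacle shape. Arc walls are annular
#' sectors between radii `R` and `R + wall_thickness`; pillars are disks
#' centred on the square inscribed in the circle of radius `R`.
#'
#' @param spec a [geometry_spec()].
#' @param spacing grid spacing in μm; must resolve the narrowest feature
#'   (at most `min(l, wall)/4`).
#' @param domain_halfwidth half-width of the square domain in μm.
#' @return an object of class `"obstacle_mask"`: list with `grid` (logical
#'   matrix, rows index x), `spacing`, `origin` (centre of cell `[1,1]`).
#' @examples
#' m <- rasterize(geometry_spec("one_channel", R = 5, arclength = 3),
#'                spacing = 0.25, domain_halfwidth = 8)
#' mean(m$grid)
#' @export
rasterize <- function(spec, spacing, domain_halfwidth) {
  stopifnot(inherits(spec, "geometry_spec"))
  stopifnot_scalar(spacing, "spacing", positive = TRUE)
  stopifnot_scalar(domain_halfwidth, "domain_halfwidth", positive = TRUE)
  if (spec$family != "none") {
    narrowest <- if (spec$family == "four_pillars") spec$arclength
                 else min(spec$arclength, spec$wall_thickness)
    if (spacing > narrowest / 4)
      stop(sprintf(paste0("spacing %.3g um is too coarse to resolve the ",
                          "narrowest feature (%.3g um); need <= %.3g um"),
                   spacing, narrowest, narrowest / 4), call. = FALSE)
  }

  half_cells <- ceiling(domain_halfwidth / spacing)
  coords <- (-half_cells:half_cells) * spacing
  n <- length(coords)
  origin <- c(coords[1] + spec$center[1], coords[1] + spec$center[2])
  xs <- coords + spec$center[1]
  ys <- coords + spec$center[2]

  grid <- matrix(FALSE, n, n)
  if (spec$family %in% c("one_channel", "four_channels")) {
    dx <- matrix(xs - spec$center[1], n, n)
    dy <- matrix(ys - spec$center[2], n, n, byrow = TRUE)
    r <- sqrt(dx^2 + dy^2)
    in_annulus <- r >= spec$R & r <= spec$R + spec$wall_thickness
    theta <- atan2(dy, dx)
    gap_half <- spec$arclength / (2 * spec$R)         # channel half-angle
    period <- 2 * pi / spec$n_channels
    dth <- abs(((theta %% period) + period) %% period - 0)
    dth <- pmin(dth, period - dth)                     # distance to channel centre
    grid <- in_annulus & (dth > gap_half)
  } else if (spec$family == "four_pillars") {
    d <- spec$R / sqrt(2)
    centers <- rbind(c(d, d), c(-d, d), c(-d, -d), c(d, -d))
    for (k in seq_len(4)) {
      dx <- matrix(xs - (spec$center[1] + centers[k, 1]), n, n)
      dy <- matrix(ys - (spec$center[2] + centers[k, 2]), n, n, byrow = TRUE)
      grid <- grid | (dx^2 + dy^2 <= spec$pillar_radius^2)
    }
  }
  structure(list(grid = grid, spacing = spacing, origin = origin),
            class = "obstacle_mask")
}

#' @export
print.obstacle_mask <- function(x, ...) {
  cat(sprintf("<obstacle_mask> %d x %d cells, spacing %.4g um, %.1f%% obstacle\n",
              nrow(x$grid), ncol(x$grid), x$spacing, 100 * mean(x$grid)))
  invisible(x)
}

#' Obstacle area of a rasterized mask
#'
#' @param mask an [rasterize()] result.
#' @return obstacle area in μm².
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "obstacle_mask"))
  sum(mask$grid) * mask$spacing^2
}

#' Read / write a geometry configuration
#'
#' Geometry configs are YAML (or JSON) files with keys `family`, `R_um`,
#' `n_channels`, `arclength_um`, `pillar_radius_um`, `wall_thickness_um`,
#' `center_um`.
#'
#' @param path file path.
#' @return `read_geometry_config` returns a [geometry_spec()];
#'   `write_geometry_config` returns `path` invisibly.
#' @export
read_geometry_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  geometry_spec(family = cfg$family,
                R = cfg$R_um %||% 12.25,
                arclength = cfg$arclength_um,
                pillar_radius = cfg$pillar_radius_um,
                wall_thickness = cfg$wall_thickness_um %||% 1.0,
                center = cfg$center_um %||% c(0, 0))
}

#' @param spec a [geometry_spec()] to write.
#' @rdname read_geometry_config
#' @export
write_geometry_config <- function(spec, path) {
  stopifnot(inherits(spec, "geometry_spec"))
  cfg <- list(family = spec$family, R_um = spec$R,
              n_channels = spec$n_channels, arclength_um = spec$arclength,
              pillar_radius_um = spec$pillar_radius,
              wall_thickness_um = spec$wall_thickness,
              center_um = spec$center)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export an obstacle mask as a portable text grid
#'
#' Writes a one-line header `# spacing_um=<s> origin_um=<x>,<y>` followed by
#' one row of 0/1 per y line (x across), for quick external inspection.
#'
#' @param mask an `obstacle_mask`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "obstacle_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spacing_um=%g origin_um=%g,%g",
                     mask$spacing, mask$origin[1], mask$origin[2]), con)
  g <- mask$grid
  for (iy in seq_len(ncol(g)))
    writeLines(paste0(as.integer(g[, iy]), collapse = ""), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
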