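# Analytical narrow-escape comparison models. None has adjustable
# parameters: each maps a confinement geometry to a normalized effective
# diffusion D_eff/D0 through a single documented escape-time bijection.

# Mean first-passage time from a uniform start in a fully absorbing disk:
# tau_ref = R^2 / (8 D). Every escape-time model is normalized by this
# same fully-open anchor, so cross-model ordering does not depend on the
# mapping.
tau_open_disk <- function(R, D) R^2 / (8 * D)

escape_prediction <- function(model, sigma, family, d_ratio,
                              mean_escape_time = NA_real_) {
  structure(list(model = model, sigma = sigma, family = family,
                 d_ratio = d_ratio, mean_escape_time = mean_escape_time),
            class = "escape_prediction")
}

#' @export
print.escape_prediction <- function(x, ...) {
  cat(sprintf("<escape_prediction> %s: sigma=%.4g D_eff/D0=%.4g tau=%.4g s\n",
              x$model, x$sigma, x$d_ratio, x$mean_escape_time))
  invisible(x)
}

#' Narrow-escape-time model for a circular disk (NET)
#'
#' Small-window asymptotics for the mean first-passage time of a Brownian
#' particle, started uniformly in a disk of radius `R`, to a single
#' absorbing boundary arc of angular fraction `sigma`:
#' `tau = (R^2/D) * (ln(1/eps) + ln 2 + 1/8)` with `eps = pi*sigma` the
#' absorbing half-angle. The asymptotics are only controlled for small
#' windows; consistent with reported experience, a warning is issued for
#' `sigma > 0.05`, and sigmas large enough to make the leading term
#' nonpositive are rejected outright.
#'
#' @param sigma absorbing fraction of the circumference, in `(0, 1)`.
#' @param R disk radius in μm.
#' @param D local diffusion coefficient in μm²/s.
#' @return an `"escape_prediction"` with the mean escape time and the
#'   normalized effective diffusion `d_ratio = tau_ref / tau`,
#'   `tau_ref = R^2/(8D)`.
#' @export
net_disk <- function(sigma, R = 12.25, D = 2.92) {
  stopifnot_scalar(sigma, "sigma")
  if (sigma <= 0 || sigma >= 1)
    stop("`sigma` must lie in (0, 1)", call. = FALSE)
  if (sigma > 0.05)
    warning("NET asymptotics degrade beyond sigma = 0.05", call. = FALSE)
  eps <- pi * sigma
  lead <- log(1 / eps) + log(2) + 1 / 8
  if (lead <= 1 / 8)
    stop(sprintf("sigma = %g is outside the NET model's validity", sigma),
         call. = FALSE)
  tau <- R^2 / D * lead
  escape_prediction("net_disk", sigma, "one_channel",
                    d_ratio = tau_open_disk(R, D) / tau,
                    mean_escape_time = tau)
}

#' Boundary-homogenization model (patchy absorbing circle)
#'
#' Replaces the alternating reflecting/absorbing boundary (n equally
#' spaced absorbing arcs, total fraction `sigma`) by a uniform partially
#' absorbing one with effective trapping rate
#' `kappa = pi D / (L ln(1/sin(pi sigma / 2)))`, `L = 2 pi R / n` the
#' boundary period, giving the uniform-start mean escape time
#' `tau = R/(2 kappa) + R^2/(8D)
#'      = (R^2/D) * (ln(1/sin(pi sigma/2))/n + 1/8)`.
#' At `sigma = 1` this is exactly the perfectly absorbing disk, the same
#' anchor the NET model is normalized by.
#'
#' @param sigma absorbing fraction in `(0, 1]`.
#' @param n_channels number of absorbing arcs, `>= 1`.
#' @inheritParams net_disk
#' @return an `"escape_prediction"`.
#' @export
boundary_homogenization <- function(sigma, n_channels = 1L, R = 12.25,
                                    D = 2.92) {
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  if (sigma > 1) stop("`sigma` must be <= 1", call. = FALSE)
  if (n_channels < 1L) stop("`n_channels` must be >= 1", call. = FALSE)
  tau <- R^2 / D * (log(1 / sin(pi * sigma / 2)) / n_channels + 1 / 8)
  family <- if (n_channels == 1L) "one_channel" else "four_channels"
  escape_prediction("boundary_homogenization", sigma, family,
                    d_ratio = tau_open_disk(R, D) / tau,
                    mean_escape_time = tau)
}

# pillar area fraction on the square lattice of constant R*sqrt(2)
pillar_area_fraction <- function(spec) {
  stopifnot(inherits(spec, "geometry_spec"))
  if (spec$family != "four_pillars")
    stop("pillar models require family \"four_pillars\"", call. = FALSE)
  pi * spec$pillar_radius^2 / (2 * spec$R^2)
}

#' Rayleigh multipole model for the pillar array
#'
#' Effective diffusion through a square array of reflecting circular
#' pillars via Rayleigh's multipole expansion in the pillar area fraction
#' `phi` (Perrins-McKenzie-McPhedran coefficients for the square lattice):
#' `D_eff/D0 = 1 - 2 phi / (1 + phi - 0.305827 phi^4 / (1 - 1.402958 phi^8))`.
#' This reduces to the dilute result `(1-phi)/(1+phi)` at small `phi`,
#' tends to 1 as the pillars vanish, and collapses toward 0 as pillars
#' approach touching (`phi -> pi/4`).
#'
#' @param spec a four-pillar [geometry_spec()].
#' @param D local diffusion coefficient in μm²/s.
#' @return an `"escape_prediction"` (no escape time: this is an
#'   effective-medium model, already on the D_eff/D0 axis).
#' @export
rayleigh_pillars <- function(spec, D = 2.92) {
  phi <- pillar_area_fraction(spec)
  if (phi >= pi / 4)
    stop("pillars overlap (area fraction >= pi/4)", call. = FALSE)
  d_ratio <- 1 - 2 * phi / (1 + phi - 0.305827 * phi^4 / (1 - 1.402958 * phi^8))
  escape_prediction("rayleigh", unobstructed_fraction(spec), "four_pillars",
                    d_ratio = d_ratio)
}

#' Perturbation-expansion model for the pillar array
#'
#' Second-order perturbation expansion of the effective diffusivity of a
#' square array of reflecting pillars in the area fraction:
#' `D_eff/D0 = 1 - 2 phi + 2 phi^2`. Agrees with [rayleigh_pillars()] at
#' low and moderate pillar fractions and, as a truncated series must,
#' departs from it as the pillars approach touching.
#'
#' @inheritParams rayleigh_pillars
#' @return an `"escape_prediction"`.
#' @export
perturbation_pillars <- function(spec, D = 2.92) {
  phi <- pillar_area_fraction(spec)
  if (phi >= pi / 4)
    stop("pillars overlap (area fraction >= pi/4)", call. = FALSE)
  d_ratio <- 1 - 2 * phi + 2 * phi^2
  escape_prediction("perturbation", unobstructed_fraction(spec),
                    "four_pillars", d_ratio = d_ratio)
}

#' Compare analytical models and PDE numerics on a sigma grid
#'
#' Tabulates each applicable model's normalized effective diffusion
#' `D_eff/D0` per sigma for one geometry family, optionally alongside the
#' numeric column obtained by simulating the FRAP protocol with
#' [effective_diffusion()] and normalizing by the unobstructed case.
#' Models that do not apply to a family are `NA`, not zero.
#'
#' @param family geometry family.
#' @param sigma_grid unobstructed fractions in `(0, 1)`.
#' @param R confinement radius in μm.
#' @param D local diffusion coefficient in μm²/s.
#' @param numeric run the PDE simulation column (slower).
#' @param spacing,halfwidth_factor,record_times PDE discretization controls
#'   for the numeric column (see [frap_domain()]).
#' @param csv optional path to also write the table as CSV.
#' @return data.frame with columns `family`, `sigma`, one column per model
#'   (`net_disk`, `boundary_homogenization`, `rayleigh`, `perturbation`)
#'   and `numeric` when requested.
#' @export
compare_models <- function(family = c("four_pillars", "four_channels",
                                      "one_channel"),
                           sigma_grid, R = 12.25, D = 2.92,
                           numeric = FALSE, spacing = 0.15,
                           halfwidth_factor = 2.5,
                           record_times = NULL, csv = NULL) {
  family <- match.arg(family)
  if (any(sigma_grid <= 0 | sigma_grid >= 1))
    stop("sigma grid must lie in (0, 1)", call. = FALSE)
  n_ch <- switch(family, one_channel = 1L, four_channels = 4L,
                 four_pillars = 4L)
  rows <- lapply(sigma_grid, function(s) {
    net <- if (family == "one_channel")
      tryCatch(suppressWarnings(net_disk(s, R, D))$d_ratio,
               error = function(e) NA_real_) else NA_real_
    bh <- if (family != "four_pillars")
      boundary_homogenization(s, n_ch, R, D)$d_ratio else NA_real_
    ray <- pert <- NA_real_
    if (family == "four_pillars") {
      spec <- sigma_sweep("four_pillars", s, R = R)[[1]]
      ray <- rayleigh_pillars(spec, D)$d_ratio
      pert <- perturbation_pillars(spec, D)$d_ratio
    }
    data.frame(family = family, sigma = s, net_disk = net,
               boundary_homogenization = bh, rayleigh = ray,
               perturbation = pert)
  })
  out <- do.call(rbind, rows)
  if (numeric) {
    out$numeric <- vapply(sigma_grid, function(s) {
      numeric_d_ratio(family, s, R, D, spacing, halfwidth_factor,
                      record_times)
    }, numeric(1))
  }
  if (!is.null(csv)) write.csv(out, csv, row.names = FALSE)
  out
}

# PDE-numeric D_eff/D0 for one geometry at one sigma, normalized by the
# identically discretized unobstructed run
numeric_d_ratio <- function(family, sigma, R, D, spacing = 0.15,
                            halfwidth_factor = 2.5, record_times = NULL) {
  spec <- sigma_sweep(family, sigma, R = R)[[1]]
  if (is.null(record_times)) {
    t_free <- R^2 / (4 * D)
    record_times <- seq(t_free / 40, 12 * t_free / max(sigma, 0.1),
                        length.out = 240)
  }
  proto <- frap_protocol(bleach_radius = R, record_times = record_times)
  mask <- frap_domain(spec, spacing = spacing,
                      halfwidth_factor = halfwidth_factor)
  free_mask <- frap_domain(geometry_spec("none", R = R), spacing = spacing,
                           halfwidth_factor = halfwidth_factor)
  D_obs <- effective_diffusion(mask, D, proto)$D_eff
  D_free <- effective_diffusion(free_mask, D, proto)$D_eff
  normalize_to_reference(D_obs, D_free)
}

#' Plot a model-comparison table
#'
#' Thin ggplot2 layer over [compare_models()] output; all information is in
#' the CSV, the figure just redraws it.
#'
#' @param tab a [compare_models()] data.frame.
#' @return a ggplot object.
#' @export
plot_model_comparison <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  cols <- setdiff(names(tab), c("family", "sigma"))
  long <- do.call(rbind, lapply(cols, function(cn) {
    data.frame(family = tab$family, sigma = tab$sigma, model = cn,
               d_ratio = tab[[cn]])
  }))
  long <- long[is.finite(long$d_ratio), ]
  ggplot2::ggplot(long, ggplot2::aes(x = sigma, y = d_ratio,
                                     colour = model)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "unobstructed fraction σ",
                  y = expression(D[eff] / D[0])) +
    ggplot2::theme_minimal()
}
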