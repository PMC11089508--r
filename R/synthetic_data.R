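# Synthetic-data generator: emulates the experimental campaign (noisy FRAP
# recoveries over a sigma sweep, FCS acquisition series) so every pipeline
# stage is testable by parameter recovery with no external download.

#' Noise model for synthetic detectors
#'
#' FRAP read noise is multiplicative Gaussian on the normalized intensity;
#' FCS shot noise is Poisson on binned counts.
#'
#' @param relative_gaussian_sd relative SD applied per FRAP sample
#'   (default 0.01, i.e. 1% read noise).
#' @param poisson_shot apply Poisson shot noise to FCS counts.
#' @param seed RNG seed for the dataset.
#' @return a `"noise_model"` list.
#' @export
noise_model <- function(relative_gaussian_sd = 0.01, poisson_shot = TRUE,
                        seed = 1L) {
  if (relative_gaussian_sd < 0)
    stop("`relative_gaussian_sd` must be >= 0", call. = FALSE)
  structure(list(relative_gaussian_sd = relative_gaussian_sd,
                 poisson_shot = isTRUE(poisson_shot), seed = seed),
            class = "noise_model")
}

#' Generate a synthetic FRAP dataset over a sigma sweep
#'
#' For each requested unobstructed fraction, simulates the FRAP protocol
#' with the zero-flux PDE solver, applies the FRAP noise model, and
#' returns the noisy traces together with a truth table recording the
#' generating sigma, the input `D_true` and the effective diffusion
#' coefficient fitted from the noiseless solver output.
#'
#' @param family geometry family (`"none"` runs a single unobstructed
#'   reference).
#' @param sigma_values unobstructed fractions in `(0, 1]`.
#' @param D_true local diffusion coefficient in μm²/s (default the
#'   outside-pattern 2.92 μm²/s).
#' @param R_b bleach/confinement radius in μm (default 12.25 μm).
#' @param noise a [noise_model()].
#' @param seed dataset seed (overrides `noise$seed` when given).
#' @param spacing,halfwidth_factor solver discretization (see
#'   [frap_domain()]).
#' @param record_times recording grid in s (default spans the expected
#'   recovery).
#' @param bleach_depth bleach depth (default 0.9, a deep bleach).
#' @param out_dir optional directory: writes `traces/*.csv`, `truth.csv`,
#'   `config.yaml` and `MANIFEST.json`.
#' @return list with `traces` (named list of [recovery_trace()]) and
#'   `truth` (data.frame sigma, family, D_true, D_eff_noiseless).
#' @export
make_frap_dataset <- function(family = c("four_channels", "one_channel",
                                         "four_pillars", "none"),
                              sigma_values = c(0.1, 0.2, 0.3, 0.5, 0.8),
                              D_true = 2.92, R_b = 12.25,
                              noise = noise_model(), seed = NULL,
                              spacing = 0.15, halfwidth_factor = 2.5,
                              record_times = NULL, bleach_depth = 0.9,
                              out_dir = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(noise, "noise_model"))
  seed <- seed %||% noise$seed
  if (family == "none") sigma_values <- 1
  if (is.null(record_times)) {
    t_free <- R_b^2 / (4 * D_true)
    record_times <- seq(t_free / 40, 10 * t_free / min(max(sigma_values, 0.1), 1),
                        length.out = 200)
  }
  proto <- frap_protocol(bleach_radius = R_b, bleach_depth = bleach_depth,
                         record_times = record_times)
  specs <- if (family == "none") list(geometry_spec("none", R = R_b))
           else sigma_sweep(family, sigma_values, R = R_b)
  traces <- list(); truth <- NULL
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    mask <- frap_domain(spec, spacing = spacing,
                        halfwidth_factor = halfwidth_factor)
    clean <- simulate_frap(mask, D_true, proto)
    fit <- fit_recovery(clean)
    noisy <- clean
    if (noise$relative_gaussian_sd > 0) {
      noisy$intensity_norm <- with_seed(sub_seed(seed, i),
        clean$intensity_norm *
          (1 + rnorm(nrow(clean), 0, noise$relative_gaussian_sd)))
    }
    nm <- sprintf("%s_sigma%.4g", spec$family, sigma_values[i])
    traces[[nm]] <- noisy
    truth <- rbind(truth,
                   data.frame(name = nm, family = spec$family,
                              sigma = sigma_values[i], D_true = D_true,
                              D_eff_noiseless = fit$D))
  }
  out <- list(traces = traces, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "traces"), recursive = TRUE,
               showWarnings = FALSE)
    for (nm in names(traces))
      write_recovery_trace(traces[[nm]],
                           file.path(out_dir, "traces", paste0(nm, ".csv")))
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    yaml::write_yaml(list(family = family, sigma = sigma_values,
                          D_true = D_true, R_um = R_b, spacing_um = spacing,
                          halfwidth_factor = halfwidth_factor,
                          bleach_depth = bleach_depth,
                          noise_sd = noise$relative_gaussian_sd),
                     file.path(out_dir, "config.yaml"))
    jsonlite::write_json(list(seed = seed, package = "confineR",
                              version = as.character(utils::packageVersion("confineR"))),
                         file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Generate a synthetic FCS acquisition series
#'
#' Mirrors the acquisition protocol (default 10 acquisitions of 5 s at the
#' pattern centre) with the Brownian-dynamics tracer simulator, each
#' acquisition under a distinct sub-seed.
#'
#' @param family geometry family, or `"none"` for a free bilayer.
#' @param sigma unobstructed fraction when a confined family is used.
#' @param D_true diffusion coefficient in μm²/s.
#' @param w beam waist in μm.
#' @param n_acq acquisitions (default 10).
#' @param duration per-acquisition duration in s (default 5 s).
#' @param R confinement radius in μm.
#' @param mean_N mean molecules in the detection area.
#' @param noise a [noise_model()] (`poisson_shot` drives shot noise).
#' @param seed dataset seed.
#' @param spacing rasterization spacing for confined families, μm.
#' @param sample_dt binning interval in s.
#' @return list with `traces` (list of intensity data.frames), `truth`
#'   (D_true, w, expected `T_D = w^2/(4 D_true)`), and `geometry`.
#' @export
make_fcs_dataset <- function(family = c("none", "one_channel",
                                        "four_channels", "four_pillars"),
                             sigma = 0.1, D_true = 2.92, w = 0.191,
                             n_acq = 10L, duration = 5, R = 12.25,
                             mean_N = 1, noise = noise_model(), seed = NULL,
                             spacing = 0.15, sample_dt = 5e-5) {
  family <- match.arg(family)
  stopifnot(inherits(noise, "noise_model"))
  seed <- seed %||% noise$seed
  mask <- NULL; box <- NULL
  if (family != "none") {
    spec <- sigma_sweep(family, sigma, R = R)[[1]]
    # domain trimmed to the pattern: the beam sits at the centre, R >> w
    mask <- rasterize(spec, spacing = spacing,
                      domain_halfwidth = R + spec$wall_thickness + 2)
  } else {
    box <- 2.5  # free patch, walls far outside the detection area
  }
  traces <- lapply(seq_len(n_acq), function(k) {
    fcs_trace(mask = mask, D = D_true, beam_center = c(0, 0), w = w,
              duration = duration, sample_dt = sample_dt, mean_N = mean_N,
              shot_noise = noise$poisson_shot, box_halfwidth = box,
              seed = sub_seed(seed, k))
  })
  list(traces = traces,
       truth = data.frame(family = family,
                          sigma = if (family == "none") 1 else sigma,
                          D_true = D_true, w = w,
                          T_D_expected = w^2 / (4 * D_true)),
       geometry = family)
}

#' Recover a diffusion coefficient from an FCS dataset
#'
#' The full local-probe analysis chain: multi-tau autocorrelation of each
#' acquisition, 2D-model fit, arithmetic averaging of `T_D` and `N` across
#' acquisitions, and conversion of the averaged `T_D` through the beam
#' waist.
#'
#' @param dataset a [make_fcs_dataset()] result (or any list of intensity
#'   data.frames with a `sample_dt` attribute under `$traces`).
#' @param w beam waist in μm.
#' @return an [aggregate_acquisitions()] result.
#' @export
recover_fcs_diffusion <- function(dataset, w = 0.191) {
  fits <- lapply(dataset$traces, function(tr) {
    corr <- autocorrelate(tr$intensity, attr(tr, "sample_dt"))
    fit_fcs(corr)
  })
  aggregate_acquisitions(fits, w = w, allow_one = length(fits) == 1L)
}

#' Write the small packaged fixture suite
#'
#' Regenerates the plain-text fixtures shipped under `inst/extdata`: three
#' FRAP traces (free, four_channels at sigma 0.1, one_channel at sigma
#' 0.1; coarse solver settings, 1% noise) and one FCS correlation table
#' from a free-bilayer tracer run. Deterministic under the fixed seed.
#'
#' @param dir output directory.
#' @param seed RNG seed (fixed default so the shipped files reproduce).
#' @return invisibly, the written paths.
#' @export
write_fixture_suite <- function(dir, seed = 20260920) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  grab <- function(ds) ds$traces[[1]]
  free <- make_frap_dataset("none", D_true = 2.92, R_b = 6, seed = seed,
                            spacing = 0.2, halfwidth_factor = 3,
                            noise = noise_model(0.01))
  fc <- make_frap_dataset("four_channels", sigma_values = 0.1, R_b = 6,
                          seed = seed + 1, spacing = 0.12,
                          halfwidth_factor = 3, noise = noise_model(0.01))
  oc <- make_frap_dataset("one_channel", sigma_values = 0.1, R_b = 6,
                          seed = seed + 2, spacing = 0.12,
                          halfwidth_factor = 3, noise = noise_model(0.01))
  paths <- c(
    write_recovery_trace(grab(free), file.path(dir, "frap_free.csv")),
    write_recovery_trace(grab(fc),
                         file.path(dir, "frap_four_channels_sigma0.1.csv")),
    write_recovery_trace(grab(oc),
                         file.path(dir, "frap_one_channel_sigma0.1.csv")))
  fcs <- make_fcs_dataset("none", n_acq = 1L, duration = 2,
                          seed = seed + 3)
  corr <- autocorrelate(fcs$traces[[1]]$intensity,
                        attr(fcs$traces[[1]], "sample_dt"))
  paths <- c(paths, write_corr_trace(corr, file.path(dir, "fcs_free_corr.csv")))
  invisible(paths)
}
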