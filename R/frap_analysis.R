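#' FRAP recovery trace
#'
#' A post-bleach fluorescence time series, normalized so the pre-bleach
#' level is 1.
#'
#' @param times post-bleach times in s, strictly increasing, `> 0`.
#' @param intensities normalized fluorescence at each time.
#' @param bleach_radius bleach-disk radius in μm (needed to convert the
#'   fitted characteristic time to a diffusion coefficient).
#' @param geometry free-text geometry label.
#' @return an object of class `"recovery_trace"` (also a data.frame with
#'   columns `time_s`, `intensity_norm`).
#' @export
recovery_trace <- function(times, intensities, bleach_radius = 12.25,
                           geometry = "unknown") {
  if (length(times) != length(intensities))
    stop("`times` and `intensities` lengths differ", call. = FALSE)
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("`times` must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities < -0.05) ||
      any(intensities > 1.5))
    stop("`intensities` must be finite normalized fluorescence", call. = FALSE)
  structure(data.frame(time_s = as.numeric(times),
                       intensity_norm = as.numeric(intensities)),
            bleach_radius = bleach_radius, geometry = geometry,
            class = c("recovery_trace", "data.frame"))
}

#' Read / write a recovery trace as CSV
#'
#' CSV columns are `time_s`, `intensity_norm`; an optional JSON sidecar
#' `<path>.json` carries `R_um` and `geometry`.
#'
#' @param path CSV path.
#' @param bleach_radius bleach radius in μm, used when no sidecar exists.
#' @return a [recovery_trace()].
#' @export
read_recovery_trace <- function(path, bleach_radius = 12.25) {
  d <- read.csv(path)
  geometry <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    bleach_radius <- meta$R_um %||% bleach_radius
    geometry <- meta$geometry %||% geometry
  }
  recovery_trace(d$time_s, d$intensity_norm, bleach_radius, geometry)
}

#' @param trace a [recovery_trace()] to write.
#' @rdname read_recovery_trace
#' @export
write_recovery_trace <- function(trace, path) {
  stopifnot(inherits(trace, "recovery_trace"))
  write.csv(data.frame(time_s = trace$time_s,
                       intensity_norm = trace$intensity_norm),
            path, row.names = FALSE)
  jsonlite::write_json(list(R_um = attr(trace, "bleach_radius"),
                            geometry = attr(trace, "geometry")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Soumpasis recovery kernel
#'
#' The closed-form fractional recovery for uniform-disk bleaching and free
#' 2D diffusion, `K(x) = exp(-2x) * (I0(2x) + I1(2x))` with `I0`, `I1` the
#' modified Bessel functions of the first kind of orders 0 and 1 and
#' `x = T/t` the characteristic time over elapsed time. `K` decreases
#' strictly from 1 (at `x = 0`, full recovery) to 0 (`x -> Inf`, just after
#' the bleach).
#'
#' @param x dimensionless `T/t`, `>= 0`.
#' @return recovered fraction in `[0, 1]`.
#' @examples
#' soumpasis_kernel(1)  # 0.5238
#' @export
soumpasis_kernel <- function(x) {
  if (any(x < 0)) stop("`x` must be >= 0", call. = FALSE)
  # expon.scaled Bessel keeps the product finite for large x
  out <- besselI(2 * x, 0, expon.scaled = TRUE) +
         besselI(2 * x, 1, expon.scaled = TRUE)
  out[x == 0] <- 1
  out
}

# recovery model: I(t) = I0 + sum_n A_n * K((T_n / t)^alpha)
frap_model <- function(t, I0, A, Tn, alpha = 1) {
  stopifnot(length(A) == length(Tn))
  acc <- rep(I0, length(t))
  for (n in seq_along(A))
    acc <- acc + A[n] * soumpasis_kernel((Tn[n] / t)^alpha)
  acc
}

# x at which the kernel equals half recovery; used to initialize T from the
# observed half-recovery time
kernel_half_x <- function() {
  uniroot(function(x) soumpasis_kernel(x) - 0.5, c(0.5, 2), tol = 1e-10)$root
}

frap_start_values <- function(trace, n_species) {
  I0 <- trace$intensity_norm[1]
  plateau <- mean(utils::tail(trace$intensity_norm, max(3L, nrow(trace) %/% 20)))
  amp <- max(plateau - I0, 1e-3)
  mid <- I0 + amp / 2
  above <- which(trace$intensity_norm >= mid)
  t_half <- if (length(above)) trace$time_s[above[1]]
            else utils::tail(trace$time_s, 1)
  T0 <- max(kernel_half_x() * t_half, 1e-6)
  if (n_species == 1L) list(I0 = I0, A = amp, T = T0)
  else {
    # split amplitude evenly, spread times geometrically around T0
    sp <- 4^(seq_len(n_species) - (n_species + 1) / 2)
    list(I0 = I0, A = rep(amp / n_species, n_species), T = T0 * sp)
  }
}

#' Fit the Soumpasis recovery model to a FRAP trace
#'
#' Unweighted least-squares fit of
#' `I(t) = I0 + sum_n A_n * K(T_n / t)` with [soumpasis_kernel()] `K`,
#' by Levenberg-Marquardt with a deterministic derivative-free start
#' (`I0` from the first point, amplitude from the plateau, `T` from the
#' half-recovery time via kernel inversion).
#'
#' @param trace a [recovery_trace()] with at least 10 points.
#' @param n_species number of diffusing species (the protocol data are
#'   satisfied by 1).
#' @return an object of class `"frap_fit"`: list with `I0`, `amplitudes`,
#'   `times` (characteristic times `T_n`, s), `alpha` (NA here), `D`
#'   (μm²/s from the slowest-species-free conversion `R^2/(4T)` of the
#'   dominant `T`), `uncertainties`, `residual_rms`, `converged`,
#'   `ill_conditioned` (parameter correlation > 0.99), and the input trace.
#' @export
fit_recovery <- function(trace, n_species = 1L) {
  stopifnot(inherits(trace, "recovery_trace"))
  n_species <- as.integer(n_species)
  if (n_species < 1L) stop("`n_species` must be >= 1", call. = FALSE)
  if (nrow(trace) < 10L)
    stop("need at least 10 time points to fit", call. = FALSE)
  if (diff(range(trace$intensity_norm)) < 1e-6)
    stop("flat trace: no recovery to fit (characteristic time unbounded)",
         call. = FALSE)
  st <- frap_start_values(trace, n_species)
  par0 <- c(I0 = st$I0, setNames(st$A, paste0("A", seq_len(n_species))),
            setNames(st$T, paste0("T", seq_len(n_species))))
  fit <- fit_frap_lm(trace, par0, n_species, alpha_free = FALSE)
  fit$n_species <- n_species
  fit
}

# shared LM machinery for the Brownian and anomalous fits
fit_frap_lm <- function(trace, par0, n_species, alpha_free) {
  t <- trace$time_s; y <- trace$intensity_norm
  residfun <- function(p) {
    A <- p[paste0("A", seq_len(n_species))]
    Tn <- abs(p[paste0("T", seq_len(n_species))])
    alpha <- if (alpha_free) abs(p["alpha"]) else 1
    frap_model(t, p["I0"], A, Tn, alpha) - y
  }
  res <- minpack.lm::nls.lm(par = par0, fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (res$info < 1 || res$info > 4)
    stop("recovery fit did not converge: ", res$message, call. = FALSE)
  p <- res$par
  Tn <- abs(p[paste0("T", seq_len(n_species))])
  A <- p[paste0("A", seq_len(n_species))]
  R <- attr(trace, "bleach_radius")
  dom <- which.max(A)                     # dominant species sets D
  unc <- rep(NA_real_, length(p))
  ill <- FALSE
  cv <- tryCatch(vcov(res), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(cv))) {
    unc <- sqrt(pmax(diag(cv), 0))
    cm <- suppressWarnings(stats::cov2cor(cv))
    off <- abs(cm[upper.tri(cm)])
    ill <- any(is.finite(off) & off > 0.99)
  }
  names(unc) <- names(p)
  rms <- sqrt(mean(res$fvec^2))
  span_ok <- t[1] <= 0.2 * Tn[dom] && max(t) >= 5 * Tn[dom]
  structure(list(I0 = unname(p["I0"]), amplitudes = unname(A),
                 time_span_ok = span_ok,
                 times = unname(Tn),
                 alpha = if (alpha_free) unname(abs(p["alpha"])) else NA_real_,
                 D = unname(diffusion_from_time(Tn[dom], R)),
                 uncertainties = unc, residual_rms = rms,
                 converged = TRUE, ill_conditioned = ill,
                 trace = trace),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> T = %s s, D = %.4g um^2/s, rms = %.2e\n",
              paste(signif(x$times, 4), collapse = ", "), x$D,
              x$residual_rms))
  if (!is.na(x$alpha)) cat(sprintf("  anomalous exponent alpha = %.4f\n", x$alpha))
  if (isTRUE(x$ill_conditioned)) cat("  warning: parameters highly correlated (> 0.99)\n")
  invisible(x)
}

#' Fit the anomalous-diffusion recovery model
#'
#' Generalizes the Brownian model by replacing the kernel argument `T/t`
#' with `(T/t)^alpha`; `alpha = 1` reduces exactly to [fit_recovery()]
#' (free Brownian diffusion), and sub-diffusive traces yield `alpha < 1`.
#'
#' @inheritParams fit_recovery
#' @return a `"frap_fit"` with the fitted `alpha` filled in.
#' @export
fit_anomalous <- function(trace) {
  stopifnot(inherits(trace, "recovery_trace"))
  if (nrow(trace) < 10L)
    stop("need at least 10 time points to fit", call. = FALSE)
  if (diff(range(trace$intensity_norm)) < 1e-6)
    stop("flat trace: no recovery to fit", call. = FALSE)
  st <- frap_start_values(trace, 1L)
  par0 <- c(I0 = st$I0, A1 = st$A, T1 = st$T, alpha = 1)
  fit <- fit_frap_lm(trace, par0, 1L, alpha_free = TRUE)
  fit$n_species <- 1L
  fit
}

#' Diffusion coefficient from a FRAP characteristic time
#'
#' `D = R^2 / (4 T)` with `R` the radius of the bleached region.
#'
#' @param T characteristic diffusion time in s.
#' @param R bleach radius in μm.
#' @return D in μm²/s.
#' @examples
#' diffusion_from_time(12.8478, 12.25)  # ~2.92
#' @export
diffusion_from_time <- function(T, R) {
  stopifnot_scalar(T, "T", positive = TRUE)
  stopifnot_scalar(R, "R", positive = TRUE)
  R^2 / (4 * T)
}

#' Normalize a diffusion coefficient to the outside-pattern reference
#'
#' All geometry results are reported relative to diffusion measured outside
#' the patterns, removing systematic environment differences.
#'
#' @param D_inside diffusion coefficient inside the pattern (μm²/s).
#' @param D_outside reference coefficient outside (μm²/s), `> 0`.
#' @return the ratio `D_inside / D_outside`.
#' @examples
#' normalize_to_reference(1.61, 2.92)  # ~0.551
#' @export
normalize_to_reference <- function(D_inside, D_outside) {
  if (any(D_inside <= 0) || any(D_outside <= 0))
    stop("diffusion coefficients must be > 0", call. = FALSE)
  D_inside / D_outside
}
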