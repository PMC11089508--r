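#' FCS correlation trace
#'
#' @param lags lag times in s, strictly increasing, `> 0`.
#' @param G normalized fluctuation autocorrelation at each lag.
#' @param duration acquisition duration in s (metadata).
#' @param n_acquisitions number of acquisitions averaged (metadata).
#' @return an object of class `"corr_trace"` (also a data.frame with
#'   columns `lag_s`, `G`).
#' @export
corr_trace <- function(lags, G, duration = NA_real_, n_acquisitions = 1L) {
  if (length(lags) != length(G))
    stop("`lags` and `G` lengths differ", call. = FALSE)
  if (any(lags <= 0) || any(diff(lags) <= 0))
    stop("`lags` must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(G))) stop("`G` must be finite", call. = FALSE)
  structure(data.frame(lag_s = as.numeric(lags), G = as.numeric(G)),
            duration = duration, n_acquisitions = n_acquisitions,
            class = c("corr_trace", "data.frame"))
}

#' Read / write an FCS correlation table as CSV
#'
#' Columns `lag_s`, `G`.
#' @param path CSV path.
#' @return `read_corr_trace` returns a [corr_trace()].
#' @export
read_corr_trace <- function(path) {
  d <- read.csv(path)
  corr_trace(d$lag_s, d$G)
}

#' @param corr a [corr_trace()] to write.
#' @rdname read_corr_trace
#' @export
write_corr_trace <- function(corr, path) {
  stopifnot(inherits(corr, "corr_trace"))
  write.csv(data.frame(lag_s = corr$lag_s, G = corr$G), path,
            row.names = FALSE)
  invisible(path)
}

#' Two-dimensional single-component FCS model
#'
#' `G(tau) = (1/N) / (1 + tau/T_D)` with `N` the mean molecule number in
#' the detection area and `T_D` the mean transit time through it.
#'
#' @param tau lag times in s, `>= 0`.
#' @param N mean molecules in the detection area, `> 0`.
#' @param T_D mean transit time in s, `> 0`.
#' @return model correlation amplitude.
#' @examples
#' fcs_model(0, N = 5, T_D = 3.1e-3)      # 1/5
#' fcs_model(3.1e-3, N = 5, T_D = 3.1e-3) # 1/10
#' @export
fcs_model <- function(tau, N, T_D) {
  if (any(tau < 0)) stop("`tau` must be >= 0", call. = FALSE)
  stopifnot_scalar(N, "N", positive = TRUE)
  stopifnot_scalar(T_D, "T_D", positive = TRUE)
  (1 / N) / (1 + tau / T_D)
}

#' Multi-tau autocorrelation of a binned intensity trace
#'
#' Normalized fluctuation autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` on a quasi-logarithmic lag grid:
#' the first `2m` lags at the native sampling time, then `m` lags per
#' octave with the trace re-binned by 2 at each level (`m = 8` points per
#' octave by default).
#'
#' @param intensity intensity samples at a fixed rate (counts or arbitrary
#'   units), length at least 1e4.
#' @param sample_dt sampling interval in s.
#' @param m points per octave.
#' @param max_lag largest lag to evaluate, in s (default: an eighth of the
#'   trace).
#' @return a [corr_trace()].
#' @export
autocorrelate <- function(intensity, sample_dt, m = 8L,
                          max_lag = length(intensity) * sample_dt / 8) {
  n <- length(intensity)
  if (n < 1e4) stop("need at least 1e4 samples to correlate", call. = FALSE)
  mu <- mean(intensity)
  if (sd(intensity) == 0 || mu == 0)
    stop("constant trace has no fluctuations to correlate", call. = FALSE)
  x <- as.numeric(intensity)
  lags_s <- numeric(0); G <- numeric(0)
  level <- 0L; dt_lvl <- sample_dt
  repeat {
    lag_idx <- if (level == 0L) seq_len(2L * m) else (m + 1L):(2L * m)
    for (j in lag_idx) {
      tau <- j * dt_lvl
      if (tau > max_lag || j >= length(x)) break
      nn <- length(x) - j
      g <- mean(x[seq_len(nn)] * x[j + seq_len(nn)]) / mu^2 - 1
      lags_s <- c(lags_s, tau); G <- c(G, g)
    }
    if ((2L * m + 1L) * dt_lvl * 2 > max_lag) break
    nb <- (length(x) %/% 2L) * 2L
    if (nb < 4L * m) break
    x <- (x[seq(1L, nb, by = 2L)] + x[seq(2L, nb, by = 2L)]) / 2
    dt_lvl <- dt_lvl * 2
    level <- level + 1L
  }
  o <- order(lags_s)
  corr_trace(lags_s[o], G[o], duration = n * sample_dt)
}

#' Fit the 2D diffusion model to a correlation trace
#'
#' Unweighted Levenberg-Marquardt fit of [fcs_model()] with the
#' deterministic start `N0 = 1/G(first lag)`, `T_D0` = lag at
#' half-amplitude (interpolated).
#'
#' @param corr a [corr_trace()].
#' @return an object of class `"fcs_fit"`: list with `N`, `T_D` (s),
#'   `uncertainties`, `residual_rms`, `lag_span_ok` (whether the lag grid
#'   spans `[T_D/10, 10 T_D]`), and `D`/`w` slots filled by
#'   [diffusion_from_transit()] when a waist is supplied there.
#' @export
fit_fcs <- function(corr) {
  stopifnot(inherits(corr, "corr_trace"))
  if (nrow(corr) < 8L) stop("too few lags to fit", call. = FALSE)
  if (all(abs(corr$G) < 1e-12))
    stop("correlation is identically zero: nothing to fit", call. = FALSE)
  g1 <- corr$G[1]
  if (g1 <= 0) stop("non-positive zero-lag amplitude", call. = FALSE)
  N0 <- 1 / g1
  half <- g1 / 2
  below <- which(corr$G <= half)
  T0 <- if (length(below)) {
    i <- below[1]
    if (i == 1L) corr$lag_s[1]
    else approx(corr$G[c(i - 1L, i)], corr$lag_s[c(i - 1L, i)], xout = half)$y
  } else utils::tail(corr$lag_s, 1)
  residfun <- function(p) fcs_model(corr$lag_s, abs(p["N"]), abs(p["T_D"])) - corr$G
  res <- minpack.lm::nls.lm(par = c(N = N0, T_D = T0), fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (res$info < 1 || res$info > 4)
    stop("FCS fit did not converge: ", res$message, call. = FALSE)
  N <- abs(res$par["N"]); T_D <- abs(res$par["T_D"])
  unc <- rep(NA_real_, 2)
  cv <- tryCatch(vcov(res), error = function(e) NULL)
  if (!is.null(cv) && all(is.finite(cv))) unc <- sqrt(pmax(diag(cv), 0))
  structure(list(N = unname(N), T_D = unname(T_D),
                 uncertainties = setNames(unc, c("N", "T_D")),
                 residual_rms = sqrt(mean(res$fvec^2)),
                 lag_span_ok = corr$lag_s[1] <= T_D / 10 &&
                               max(corr$lag_s) >= 10 * T_D,
                 corr = corr),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> N = %.3g, T_D = %.4g ms, rms = %.2e\n",
              x$N, 1e3 * x$T_D, x$residual_rms))
  invisible(x)
}

#' Diffusion coefficient from an FCS transit time
#'
#' `D = w^2 / (4 T_D)` with `w` the 1/e² beam waist. Uncertainty is
#' propagated in quadrature from `T_D` and `w` when supplied.
#'
#' @param T_D mean transit time in s.
#' @param w beam waist in μm (default 0.191 μm, the dye-calibrated value).
#' @param T_D_sd,w_sd optional one-sigma uncertainties.
#' @return list with `D` (μm²/s) and `D_sd`.
#' @examples
#' diffusion_from_transit(3.1233e-3, 0.191)$D  # ~2.92
#' @export
diffusion_from_transit <- function(T_D, w = 0.191, T_D_sd = NA_real_,
                                   w_sd = NA_real_) {
  stopifnot_scalar(T_D, "T_D", positive = TRUE)
  stopifnot_scalar(w, "w", positive = TRUE)
  D <- w^2 / (4 * T_D)
  rel2 <- 0
  if (is.finite(T_D_sd)) rel2 <- rel2 + (T_D_sd / T_D)^2
  if (is.finite(w_sd)) rel2 <- rel2 + (2 * w_sd / w)^2
  list(D = D, D_sd = if (rel2 > 0) D * sqrt(rel2) else NA_real_)
}

#' Calibrate the beam waist from a reference dye
#'
#' Inverse of [diffusion_from_transit()]: `w = sqrt(4 * D_known * T_D)`.
#' When several calibration transit times are given (repeated
#' acquisitions), the waist uncertainty is the sample SD of the
#' per-acquisition waists.
#'
#' @param T_D_cal calibration transit time(s) in s.
#' @param D_known reference diffusion coefficient of the calibrant in
#'   μm²/s, `> 0`.
#' @return list with `w` (μm) and `w_sd`.
#' @export
calibrate_waist <- function(T_D_cal, D_known) {
  stopifnot_scalar(D_known, "D_known", positive = TRUE)
  if (any(T_D_cal <= 0)) stop("`T_D_cal` must be > 0", call. = FALSE)
  ws <- sqrt(4 * D_known * T_D_cal)
  list(w = mean(ws), w_sd = if (length(ws) > 1) sd(ws) else NA_real_)
}

#' Aggregate repeated FCS acquisitions
#'
#' Averages `T_D` and `N` arithmetically across fits and computes the
#' diffusion coefficient from the averaged `T_D` (not from per-acquisition
#' D values), matching the acquisition-averaging protocol.
#'
#' @param fits list of [fit_fcs()] results (at least 2, unless `allow_one`).
#' @param w beam waist in μm for the D conversion.
#' @param allow_one accept a single fit (no averaging).
#' @return an `"fcs_fit"`-like list with averaged `N`, `T_D`, their sample
#'   SDs, and `D`, `D_sd`.
#' @export
aggregate_acquisitions <- function(fits, w = 0.191, allow_one = FALSE) {
  if (length(fits) == 0L) stop("no fits to aggregate", call. = FALSE)
  if (length(fits) < 2L && !allow_one)
    stop("need at least 2 acquisitions to aggregate", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "fcs_fit")))
  T_D <- vapply(fits, `[[`, numeric(1), "T_D")
  N <- vapply(fits, `[[`, numeric(1), "N")
  T_D_sd <- if (length(T_D) > 1) sd(T_D) else NA_real_
  conv <- diffusion_from_transit(mean(T_D), w,
                                 T_D_sd = if (is.na(T_D_sd)) NA_real_
                                          else T_D_sd / sqrt(length(T_D)))
  structure(list(N = mean(N), N_sd = if (length(N) > 1) sd(N) else NA_real_,
                 T_D = mean(T_D), T_D_sd = T_D_sd,
                 D = conv$D, D_sd = conv$D_sd, w = w,
                 n_acquisitions = length(fits)),
            class = "fcs_aggregate")
}

#' @export
print.fcs_aggregate <- function(x, ...) {
  cat(sprintf("<fcs_aggregate> %d acquisitions: T_D = %.4g ms, N = %.3g, D = %.4g um^2/s\n",
              x$n_acquisitions, 1e3 * x$T_D, x$N, x$D))
  invisible(x)
}
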