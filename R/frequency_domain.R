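#' Spectral analysis configuration
#'
#' Defaults encode the standard short-term HRV recipe: the tachogram is
#' resampled at 4 Hz by cubic spline, linearly detrended, Hanning-windowed,
#' zero-padded to 2048 points and Fourier transformed; band powers are summed
#' over LF 0.04-0.15 Hz and HF 0.15-0.4 Hz with half-open `[low, high)` band
#' edges so the shared 0.15 Hz boundary bin is counted exactly once (in HF).
#'
#' Total power is the sum over all bins above 0 Hz, i.e. it includes the VLF
#' range below 0.04 Hz; set `include_vlf = FALSE` to normalize LF%/HF% by
#' LF + HF instead.
#'
#' @param resample_hz resampling rate, Hz.
#' @param n_fft FFT length after zero padding.
#' @param lf_band,hf_band numeric length-2 band edges, Hz.
#' @param interp `"spline"` (cubic, default) or `"linear"`.
#' @param include_vlf logical; include sub-LF bins in total power.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(resample_hz = 4, n_fft = 2048,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                            interp = c("spline", "linear"),
                            include_vlf = TRUE) {
  interp <- match.arg(interp)
  if (lf_band[2] != hf_band[1])
    stop("spectral_config: LF upper edge must equal HF lower edge")
  structure(list(resample_hz = resample_hz, n_fft = n_fft, lf_band = lf_band,
                 hf_band = hf_band, interp = interp, include_vlf = include_vlf),
            class = "spectral_config")
}

#' Resample a tachogram onto a uniform grid
#'
#' The RR value is treated as a function of time sampled at each interval's
#' onset and interpolated (cubic spline by default) onto a uniform grid at
#' `resample_hz`. The grid spans the knots only - no extrapolation.
#'
#' @param rr an [rr_series()] with >= 4 intervals spanning >= 2 s.
#' @param cfg a [spectral_config()].
#' @return A list with fields `t` (s), `x` (ms) and `fs` (Hz).
#' @export
resample_tachogram <- function(rr, cfg = spectral_config()) {
  stopifnot(inherits(rr, "rr_series"))
  t_knot <- rr$start_times / 1000
  span <- t_knot[length(t_knot)] - t_knot[1]
  if (length(rr$rr) < 4L || span < 2)
    stop("resample_tachogram: need >= 4 intervals spanning >= 2 s")
  grid <- seq(t_knot[1], t_knot[length(t_knot)], by = 1 / cfg$resample_hz)
  x <- if (cfg$interp == "spline") {
    splinefun(t_knot, rr$rr, method = "natural")(grid)
  } else {
    approx(t_knot, rr$rr, xout = grid)$y
  }
  list(t = grid, x = x, fs = cfg$resample_hz)
}

#' Band powers of a uniformly sampled tachogram
#'
#' Pipeline: (1) remove the least-squares linear trend; (2) apply a Hanning
#' window; (3) zero-pad to `n_fft` and FFT; (4) form the one-sided power
#' spectrum; (5) rescale by a single global factor so that total power (all
#' bins > 0 Hz) equals the variance of the detrended, pre-window series -
#' the "adjusted to the variance" convention that makes band powers (ms^2)
#' independent of the taper's power loss; (6) sum bins falling in each band.
#'
#' A zero-variance input yields zero powers with `power_defined = FALSE`;
#' ratios and percentages are then `NA` rather than silently propagated NaN.
#'
#' @param u a uniform series as returned by [resample_tachogram()].
#' @param cfg a [spectral_config()].
#' @return A list of class `spectral_result` with fields `total_power`, `lf`,
#'   `hf` (ms^2), `ln_lf`, `ln_hf`, `lf_hf_ratio`, `lf_pct`, `hf_pct`,
#'   `power_defined`.
#' @export
band_powers <- function(u, cfg = spectral_config()) {
  x <- u$x
  n <- length(x)
  if (n < 4L) stop("band_powers: series too short")
  if (n > cfg$n_fft)
    stop(sprintf("band_powers: series length %d exceeds n_fft %d", n, cfg$n_fft))
  idx <- seq_len(n)
  detr <- stats::lm.fit(cbind(1, idx), x)$residuals
  v <- var(detr)
  if (v < .Machine$double.eps) {
    return(structure(list(total_power = 0, lf = 0, hf = 0,
                          ln_lf = NA_real_, ln_hf = NA_real_,
                          lf_hf_ratio = NA_real_, lf_pct = NA_real_,
                          hf_pct = NA_real_, power_defined = FALSE),
                     class = "spectral_result"))
  }
  w <- signal::hanning(n)
  xw <- c(detr * w, rep(0, cfg$n_fft - n))
  spec <- Mod(fft(xw))^2
  half <- 2:(cfg$n_fft %/% 2 + 1)          # positive frequencies incl. Nyquist
  freq <- (half - 1) * u$fs / cfg$n_fft
  p <- spec[half]
  p <- p * (v / sum(p))                    # variance adjustment (single factor)
  in_band <- function(b) freq >= b[1] & freq < b[2]
  lf <- sum(p[in_band(cfg$lf_band)])
  hf <- sum(p[in_band(cfg$hf_band)])
  total <- if (cfg$include_vlf) sum(p) else lf + hf
  structure(list(total_power = total, lf = lf, hf = hf,
                 ln_lf = log(lf), ln_hf = log(hf),
                 lf_hf_ratio = if (hf > 0) lf / hf else NA_real_,
                 lf_pct = 100 * lf / total, hf_pct = 100 * hf / total,
                 power_defined = TRUE),
            class = "spectral_result")
}

#' Full spectral pipeline for one analysis window
#'
#' Convenience wrapper: [resample_tachogram()] then [band_powers()].
#'
#' @inheritParams resample_tachogram
#' @return A `spectral_result`, see [band_powers()].
#' @export
spectral_analysis <- function(rr, cfg = spectral_config()) {
  band_powers(resample_tachogram(rr, cfg), cfg)
}
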