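#' Block-averaged power spectrum of an LFP segment
#'
#' Welch-style estimate: the segment is cut into `nfft`-sample blocks
#' (default 4096, giving a 1.2207 Hz bin spacing at 5 kHz), each block is
#' linearly detrended and Hann-tapered, periodograms are averaged across
#' blocks (default 50% overlap). Power is reported per frequency bin in
#' uV^2, scaled so that for a pure sinusoid of amplitude `A` uV the
#' band-summed power equals `A^2 / 2`, and the sum over all bins of a
#' stationary signal equals its variance (Parseval). Input samples are in
#' mV; the mV-to-uV conversion (x1000, power x1e6) happens here and only
#' here.
#'
#' @param seg A [recording()] (mV), at least `nfft` samples long.
#' @param cfg An [analysis_config()].
#' @return A list of class `"power_spectrum"`: `freqs` (Hz), `power`
#'   (uV^2 per bin), `df` (Hz), `nfft`, `n_blocks`.
#' @export
power_spectrum <- function(seg, cfg = analysis_config()) {
  stopifnot(is_recording(seg))
  nfft <- as.integer(cfg$nfft)
  x <- seg$samples * 1000  # mV -> uV
  n <- length(x)
  if (n < nfft) stop("segment shorter than one FFT block")
  if (!identical(cfg$window_name, "hann"))
    stop("only the 'hann' taper is implemented")
  step <- max(1L, as.integer(round(nfft * (1 - cfg$overlap_frac))))
  starts <- seq(1L, n - nfft + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft)
  wss <- sum(w^2)
  nfreq <- nfft %/% 2
  acc <- numeric(nfreq + 1L)
  tt <- seq_len(nfft)
  for (s in starts) {
    blk <- x[s:(s + nfft - 1L)]
    # linear detrend per block
    fit <- stats::lm.fit(cbind(1, tt), blk)
    blk <- (blk - fit$fitted.values) * w
    X <- stats::fft(blk)[1:(nfreq + 1L)]
    acc <- acc + (Mod(X)^2)
  }
  p <- acc / length(starts)
  # one-sided scaling: band-sum == variance; interior bins doubled
  p <- p * 2 / (nfft * wss)
  p[1L] <- p[1L] / 2
  if (nfft %% 2 == 0) p[nfreq + 1L] <- p[nfreq + 1L] / 2
  structure(
    list(freqs = (0:nfreq) * seg$fs / nfft, power = p,
         df = seg$fs / nfft, nfft = nfft, n_blocks = length(starts)),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, df = %.4f Hz, %d blocks\n",
              length(x$freqs), x$df, x$n_blocks))
  invisible(x)
}

#' Gamma scalar metrics from a power spectrum
#'
#' Integrated power is the discrete sum of the per-bin power over the
#' analysis band (edges inclusive); the peak is the maximum-power bin in
#' the same band (ties broken toward the lowest frequency), and the half
#' band width is computed around it by [half_band_width()]. Bins at or
#' below 1 Hz are always excluded (DC guard).
#'
#' @param ps A `power_spectrum`.
#' @param band Two-element band `(lo, hi)` in Hz; default the 20-80 Hz
#'   gamma band.
#' @return A list: `integrated_power_uV2`, `peak_power_uV2`, `peak_f_hz`,
#'   `hbw_hz` (NA when undefined).
#' @export
gamma_scalar_metrics <- function(ps, band = c(20, 80)) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (band[1] >= band[2]) stop("empty band")
  sel <- which(ps$freqs >= band[1] & ps$freqs <= band[2] & ps$freqs > 1)
  if (length(sel) == 0L) stop("band contains no frequency bins")
  pw <- ps$power[sel]
  ipk <- sel[which.max(pw)]  # which.max -> first (lowest-frequency) maximum
  list(
    integrated_power_uV2 = sum(pw),
    peak_power_uV2 = ps$power[ipk],
    peak_f_hz = ps$freqs[ipk],
    hbw_hz = half_band_width(ps, ps$freqs[ipk], band = band)
  )
}

#' Half band width at half-maximum of the spectral peak
#'
#' The frequency range at half of the peak power: the two half-maximum
#' crossings flanking the peak bin are located by linear interpolation
#' between adjacent bins and their distance returned. When a crossing is
#' never reached inside the analysis band the width is undefined and `NA`
#' is returned (never zero).
#'
#' @param ps A `power_spectrum`.
#' @param peak_f Peak frequency (Hz), normally from
#'   [gamma_scalar_metrics()].
#' @param band Search band (Hz).
#' @return Width in Hz, or `NA_real_`.
#' @export
half_band_width <- function(ps, peak_f, band = c(20, 80)) {
  sel <- which(ps$freqs >= band[1] & ps$freqs <= band[2] & ps$freqs > 1)
  f <- ps$freqs[sel]
  p <- ps$power[sel]
  i <- which.min(abs(f - peak_f))
  half <- p[i] / 2
  cross_out <- function(dir) {
    # walk away from the peak until power first drops below half-max,
    # then place the crossing by linear interpolation with the inner bin
    j <- i + dir
    while (j >= 1L && j <= length(p)) {
      if (p[j] < half) {
        inner <- j - dir
        frac <- (p[inner] - half) / (p[inner] - p[j])
        return(f[inner] + frac * (f[j] - f[inner]))
      }
      j <- j + dir
    }
    NA_real_
  }
  lo <- cross_out(-1L)
  hi <- cross_out(1L)
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  hi - lo
}

#' Slice-inclusion rule for gamma recordings
#'
#' A segment enters the gamma analysis only when its spectral peak power
#' strictly exceeds 10 uV^2 and its peak frequency strictly exceeds 20 Hz;
#' both boundaries are excluded.
#'
#' @param metrics Output of [gamma_scalar_metrics()].
#' @param cfg An [analysis_config()] carrying the thresholds.
#' @return `TRUE` or `FALSE`.
#' @export
passes_gamma_inclusion <- function(metrics, cfg = analysis_config()) {
  isTRUE(metrics$peak_power_uV2 > cfg$inclusion_peak_power_uV2 &&
           metrics$peak_f_hz > cfg$inclusion_peak_f_hz)
}
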