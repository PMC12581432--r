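#' Zero-phase FFT band-pass filter
#'
#' Frequency-domain masking filter of the kind provided by common
#' acquisition software: forward FFT of the whole trace, out-of-band bins
#' zeroed, raised-cosine transition of width `taper_hz` at each band edge,
#' inverse FFT. Zero-phase by construction.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges in Hz; `lo = 0` gives a low-pass, `hi = Inf` a
#'   high-pass. Edges are the -0 dB points, the taper extends outward below
#'   `lo` and above `hi`.
#' @param taper_hz Transition width (Hz).
#' @return Filtered numeric vector, same length as `x`.
#' @export
fft_filter <- function(x, fs, lo, hi, taper_hz = 1) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n  # absolute frequency of each FFT bin
  ramp <- function(f, f0, f1) {
    # 0 at f0, 1 at f1, raised-cosine in between
    u <- pmin(pmax((f - f0) / (f1 - f0), 0), 1)
    0.5 - 0.5 * cos(pi * u)
  }
  m <- rep(1, n)
  if (lo > 0) m <- m * ramp(f, lo - taper_hz, lo)
  if (is.finite(hi)) m <- m * (1 - ramp(f, hi, hi + taper_hz))
  Re(stats::fft(stats::fft(x) * m, inverse = TRUE)) / n
}

#' Analytic signal via the Hilbert transform
#'
#' @param x Numeric vector (should be zero-mean over the band of interest).
#' @return Complex vector `x + i H(x)`.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# sym4 (least-asymmetric Daubechies, 8 taps) decomposition low-pass filter.
.sym4_dec_lo <- c(
  -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
  0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
  -0.01260396726203783, 0.03222310060404270
)

.qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

# Stein-unbiased-risk (SURE) soft threshold for coefficients with unit
# noise SD, with the heuristic fallback to the universal threshold when
# the signal content of the level is too weak for SURE to be reliable.
.sure_threshold <- function(y) {
  n <- length(y)
  t_univ <- sqrt(2 * log(n))
  eta <- (sum(y^2) - n) / n
  crit <- (log2(n))^1.5 / sqrt(n)
  if (!is.finite(eta) || eta < crit) return(t_univ)
  a <- sort(abs(y))
  cs <- cumsum(a^2)
  k <- seq_len(n)
  # risk of soft threshold at t = a[k]
  risk <- (n - 2 * k + cs + (n - k) * a^2) / n
  t_sure <- a[which.min(risk)]
  min(t_sure, t_univ)
}

#' Discrete wavelet denoising (sym4, level-wise soft SURE threshold)
#'
#' Multi-level periodized discrete wavelet transform with the sym4
#' wavelet; detail coefficients are soft-thresholded per level, the
#' threshold chosen by Stein's unbiased risk estimate with the heuristic
#' universal-threshold fallback for near-noise-only levels (the scheme of
#' the standard toolbox denoisers). The noise scale is estimated per
#' level from the median absolute deviation of that level's details
#' (colored-noise mode; robust to sparse spikes). Used to clean the
#' 500-2250 Hz trace before unit detection.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth.
#' @param method `"sure"` (default) or `"universal"`.
#' @return Denoised vector, same length as `x`.
#' @export
wavelet_denoise <- function(x, levels = 4L, method = c("sure", "universal")) {
  method <- match.arg(method)
  n0 <- length(x)
  # pad to a multiple of 2^levels (periodized transform needs even lengths)
  block <- 2^levels
  npad <- (block - n0 %% block) %% block
  xp <- c(x, rep(x[n0], npad))

  h <- .sym4_dec_lo
  g <- .qmf(h)
  L <- length(h)

  dwt_step <- function(a, filt) {
    n <- length(a)
    out <- numeric(n / 2)
    # periodic extension: coefficient k uses samples 2k-1 .. 2k-1+L-1 (0-based 2k..)
    idx0 <- 2 * (seq_len(n / 2) - 1)           # 0-based start
    for (j in seq_len(L)) {
      out <- out + filt[j] * a[((idx0 + j - 1) %% n) + 1]
    }
    out
  }
  idwt_step <- function(a, d, h, g) {
    n <- 2 * length(a)
    out <- numeric(n)
    idx0 <- 2 * (seq_along(a) - 1)
    for (j in seq_len(L)) {
      pos <- ((idx0 + j - 1) %% n) + 1
      contrib <- h[j] * a + g[j] * d
      out[pos] <- out[pos] + contrib
    }
    out
  }

  approx_c <- xp
  details <- vector("list", levels)
  for (lev in seq_len(levels)) {
    d <- dwt_step(approx_c, g)
    a <- dwt_step(approx_c, h)
    details[[lev]] <- d
    approx_c <- a
  }
  # level-dependent noise scale (colored-noise mode): the background is
  # not white across levels, so each level gets its own robust MAD sigma
  for (lev in seq_len(levels)) {
    d <- details[[lev]]
    sigma <- stats::median(abs(d)) / 0.6745
    thr <- if (sigma == 0) 0
    else if (method == "universal") sigma * sqrt(2 * log(length(d)))
    else sigma * .sure_threshold(d / sigma)
    details[[lev]] <- sign(d) * pmax(abs(d) - thr, 0)
  }
  for (lev in rev(seq_len(levels))) {
    approx_c <- idwt_step(approx_c, details[[lev]], h, g)
  }
  approx_c[seq_len(n0)]
}

#' Indices of strict local maxima
#' @param x Numeric vector.
#' @return Integer indices `i` with `x[i-1] < x[i] >= x[i+1]` (plateaus keep
#'   their first sample).
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

#' @rdname local_maxima
#' @keywords internal
local_minima <- function(x) local_maxima(-x)
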