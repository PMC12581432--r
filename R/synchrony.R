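#' Autocorrelogram of an LFP segment
#'
#' Biased, normalized autocorrelation of the mean-subtracted trace,
#' computed via FFT (Wiener-Khinchin), so `ac(0) = 1` and all values are
#' bounded by 1. Conventionally computed over the full two-minute gamma
#' segment with lags up to a few hundred milliseconds.
#'
#' @param seg A [recording()].
#' @param max_lag_ms Largest lag to return (ms); must be far below the
#'   segment duration.
#' @return A list of class `"autocorrelogram"`: `lags_ms` (non-negative
#'   grid), `ac`, `fs`.
#' @export
autocorrelogram <- function(seg, max_lag_ms = 300) {
  stopifnot(is_recording(seg))
  n <- length(seg$samples)
  max_lag <- as.integer(round(max_lag_ms / 1000 * seg$fs))
  if (max_lag >= n) stop("max_lag_ms must be shorter than the segment")
  x <- seg$samples - mean(seg$samples)
  if (all(x == 0)) stop("constant segment has no autocorrelation")
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, numeric(nfft - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(max_lag + 1L)] / nfft
  structure(
    list(lags_ms = (0:max_lag) / seg$fs * 1000, ac = r / r[1L], fs = seg$fs),
    class = "autocorrelogram"
  )
}

# Local maximum of `ac` nearest an expected lag, searched inside
# (lo_ms, hi_ms). Returns list(lag_ms, value) or NULL.
.acg_peak_near <- function(acg, expect_ms, lo_ms, hi_ms, sign = 1) {
  sel <- which(acg$lags_ms > lo_ms & acg$lags_ms < hi_ms)
  if (length(sel) < 3L) return(NULL)
  im <- local_maxima(sign * acg$ac[sel])
  if (length(im) == 0L) return(NULL)
  cand <- sel[im]
  best <- cand[which.min(abs(acg$lags_ms[cand] - expect_ms))]
  list(lag_ms = acg$lags_ms[best], value = acg$ac[best])
}

#' Second positive peak of the autocorrelogram
#'
#' Synchrony index of a gamma rhythm: the value of the autocorrelogram's
#' local maximum nearest one oscillation period. The zero-lag maximum is
#' counted as the first positive peak, so this "2nd positive peak" sits at
#' lag `1/peak_f` (the alternative two-period convention is available via
#' `n_periods = 2`). The search window is `(0.5, 1.5) / peak_f` scaled by
#' `n_periods`.
#'
#' @param acg An [autocorrelogram()].
#' @param peak_f Gamma peak frequency (Hz) from the spectral module.
#' @param n_periods Which multiple of the period to target (default 1).
#' @return Peak value (unitless), or `NA_real_` when no local maximum lies
#'   in the window.
#' @export
second_positive_peak <- function(acg, peak_f, n_periods = 1) {
  stopifnot(inherits(acg, "autocorrelogram"), peak_f > 0)
  period_ms <- 1000 / peak_f * n_periods
  pk <- .acg_peak_near(acg, period_ms, 0.5 * period_ms, 1.5 * period_ms)
  if (is.null(pk)) NA_real_ else pk$value
}

#' Decay time constant of the autocorrelogram peaks
#'
#' Fits a decaying exponential `A * exp(-lag / tau)` to the oscillatory
#' peaks of the autocorrelogram. Longer tau means a more temporally
#' coherent rhythm.
#'
#' Two numerical safeguards make the fit robust on broadband recordings.
#' First, a one-period moving-average baseline is subtracted from the
#' autocorrelogram before peaks are measured: this cancels the slowly
#' varying offset that 1/f background adds (which would otherwise inflate
#' tau), and — being a linear, lag-invariant operation — it rescales a
#' damped cosine by a constant without touching its decay constant.
#' Second, with `use_troughs = TRUE` (default) the rectified troughs of
#' the residual are fitted alongside the peaks, doubling the number of
#' usable points inside the well-measured first few periods; for a damped
#' cosine the trough magnitudes lie on the same exponential. Peaks are
#' located within +/- 25% windows around (half-)multiples of the gamma
#' period; later peaks are down-weighted as the square of their lag
#' because their sampling error grows with window width and baseline
#' wander.
#'
#' @param acg An [autocorrelogram()].
#' @param peak_f Gamma peak frequency (Hz).
#' @param n_peaks Number of period-multiples to use (default 8).
#' @param use_troughs Also fit the rectified troughs (default TRUE).
#' @return A list: `tau_ms` (NA on failure), `r2` of the fit,
#'   `n_peaks_used`, `reason` (`"ok"`, `"too_few_peaks"`,
#'   `"non_decaying"`).
#' @export
fit_tau <- function(acg, peak_f, n_peaks = 8L, use_troughs = TRUE) {
  stopifnot(inherits(acg, "autocorrelogram"), peak_f > 0)
  period_ms <- 1000 / peak_f
  dt_ms <- 1000 / acg$fs
  # one-period moving-average baseline
  win <- as.integer(round(period_ms / dt_ms))
  if (win %% 2L == 0L) win <- win + 1L
  pad <- (win - 1L) %/% 2L
  acp <- c(rep(acg$ac[1L], pad), acg$ac,
           rep(acg$ac[length(acg$ac)], pad))
  base <- as.numeric(stats::filter(acp, rep(1 / win, win), sides = 2L))
  resid_ac <- structure(
    list(lags_ms = acg$lags_ms,
         ac = acg$ac - base[(pad + 1L):(pad + length(acg$ac))],
         fs = acg$fs),
    class = "autocorrelogram"
  )
  half <- period_ms / 2
  mm <- if (use_troughs) seq_len(2L * n_peaks) else 2L * seq_len(n_peaks)
  lags <- vals <- numeric(0)
  for (m in mm) {
    sgn <- if (m %% 2L == 0L) 1 else -1
    pk <- .acg_peak_near(resid_ac, m * half,
                         (m - 0.5) * half, (m + 0.5) * half, sign = sgn)
    if (is.null(pk)) next
    lags <- c(lags, pk$lag_ms)
    vals <- c(vals, sgn * pk$value)
  }
  if (length(vals) < 3L)
    return(list(tau_ms = NA_real_, r2 = NA_real_,
                n_peaks_used = length(vals), reason = "too_few_peaks"))
  nondecay <- stats::coef(stats::lm(vals ~ lags))[2] >= 0
  if (nondecay)
    return(list(tau_ms = NA_real_, r2 = NA_real_,
                n_peaks_used = length(vals), reason = "non_decaying"))
  # starting value from a log-space fit over the leading positive peaks
  lead <- which(vals > 0)
  lead <- lead[seq_len(min(3L, length(lead)))]
  tau0 <- if (length(lead) >= 2L) {
    sl <- stats::coef(stats::lm(log(vals[lead]) ~ lags[lead]))[[2]]
    if (is.finite(sl) && sl < 0) -1 / sl else period_ms * 2
  } else period_ms * 2
  st <- list(A = max(vals), tau = max(tau0, period_ms / 4))
  # peak-value noise grows with lag (extremum selection in wider windows,
  # baseline wander), so down-weight later peaks as 1/k^2
  w <- (period_ms / lags)^2
  fit <- try(minpack.lm::nlsLM(
    vals ~ A * exp(-lags / tau), start = st, weights = w,
    lower = c(A = 0, tau = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (!inherits(fit, "try-error") && stats::coef(fit)[["tau"]] > 0) {
    pred <- stats::fitted(fit)
    r2 <- 1 - sum((vals - pred)^2) / sum((vals - mean(vals))^2)
    return(list(tau_ms = stats::coef(fit)[["tau"]], r2 = r2,
                n_peaks_used = length(vals), reason = "ok"))
  }
  # fallback: plain log-linear fit over positive peaks
  pos <- vals > 0
  if (sum(pos) < 3L)
    return(list(tau_ms = NA_real_, r2 = NA_real_,
                n_peaks_used = length(vals), reason = "too_few_peaks"))
  lfit <- stats::lm(log(vals[pos]) ~ lags[pos])
  slope <- stats::coef(lfit)[[2]]
  if (slope >= 0)
    return(list(tau_ms = NA_real_, r2 = NA_real_,
                n_peaks_used = length(vals), reason = "non_decaying"))
  list(tau_ms = -1 / slope, r2 = summary(lfit)$r.squared,
       n_peaks_used = length(vals), reason = "ok")
}
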