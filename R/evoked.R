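#' Construct an evoked-response sweep
#'
#' @param samples Voltage samples (mV).
#' @param fs Sampling rate (Hz).
#' @param stim_times Stimulus onset times within the sweep (s).
#' @param stim_intensity_uA Stimulation intensity (uA), optional.
#' @return A list of class `"sweep"`.
#' @export
evoked_sweep <- function(samples, fs, stim_times, stim_intensity_uA = NA_real_) {
  stopifnot(fs > 0, length(samples) > 0, all(is.finite(samples)))
  if (any(stim_times < 0 | stim_times > length(samples) / fs))
    stop("stim_times must lie within the sweep")
  structure(
    list(samples = as.numeric(samples), fs = fs,
         stim_times = sort(stim_times),
         stim_intensity_uA = stim_intensity_uA),
    class = "sweep"
  )
}

# Default analysis windows (s, relative to the stimulus). The acquisition
# literature gives no canonical values; these fit standard CA3-CA1
# latencies: 1.5 ms artifact blanking, fiber volley 1.5-4 ms, fEPSP 3-20 ms,
# 5 ms pre-stimulus baseline.
.evoked_windows <- function() {
  list(blank = 1.5e-3, fv = c(1.5e-3, 4e-3), fepsp = c(3e-3, 20e-3),
       baseline = 5e-3)
}

.win_idx <- function(sweep, stim_t, w) {
  i0 <- max(1L, as.integer(round((stim_t + w[1]) * sweep$fs)) + 1L)
  i1 <- min(length(sweep$samples), as.integer(round((stim_t + w[2]) * sweep$fs)) + 1L)
  if (i1 < i0) integer(0) else i0:i1
}

.sweep_baseline <- function(sweep, stim_t) {
  w <- .evoked_windows()
  # end 0.3 ms before the stimulus so no rounding can touch the artifact
  idx <- .win_idx(sweep, stim_t, c(-w$baseline, -3e-4))
  if (length(idx) == 0L) 0 else mean(sweep$samples[idx])
}

#' fEPSP slope between 20% and 80% of the response amplitude
#'
#' The fEPSP amplitude is measured baseline-to-extremum within the fEPSP
#' window (3-20 ms post-stimulus by default, negative-going by default);
#' the slope is the least-squares line through the samples of the onset
#' limb where the deflection lies between 20% and 80% of that amplitude.
#' Reported in V/s (equal in magnitude to mV/ms).
#'
#' @param sweep A [evoked_sweep()].
#' @param stim_idx Which stimulus of the sweep (default 1).
#' @param polarity `-1` for negative-going fEPSPs (default), `+1` otherwise.
#' @param noise_floor_mV Amplitudes at or below this are reported missing.
#' @param subtract Optional numeric vector subtracted from the sweep before
#'   measurement (used for paired-pulse overlap correction).
#' @return A list: `slope_V_per_s`, `amplitude_mV`, `t_extremum_s`
#'   (all NA when no measurable deflection).
#' @export
fepsp_slope <- function(sweep, stim_idx = 1L, polarity = -1,
                        noise_floor_mV = 0.02, subtract = NULL) {
  stopifnot(inherits(sweep, "sweep"))
  w <- .evoked_windows()
  stim_t <- sweep$stim_times[stim_idx]
  x <- sweep$samples
  if (!is.null(subtract)) x <- x - subtract
  base <- .sweep_baseline(sweep, sweep$stim_times[1L])
  win <- w$fepsp
  # a later stimulus truncates this response's analysis window
  nxt <- sweep$stim_times[sweep$stim_times > stim_t + 1e-9]
  if (length(nxt) > 0L)
    win[2L] <- min(win[2L], nxt[1L] - stim_t - 5e-4)
  idx <- .win_idx(sweep, stim_t, win)
  if (length(idx) < 4L)
    return(list(slope_V_per_s = NA_real_, amplitude_mV = NA_real_,
                t_extremum_s = NA_real_))
  d <- polarity * (x[idx] - base)  # deflection, positive toward extremum
  ipk <- which.max(d)
  amp <- d[ipk]
  if (!is.finite(amp) || amp <= noise_floor_mV)
    return(list(slope_V_per_s = NA_real_, amplitude_mV = NA_real_,
                t_extremum_s = NA_real_))
  # onset limb: from the window start up to the extremum
  limb <- seq_len(ipk)
  sel <- limb[d[limb] >= 0.2 * amp & d[limb] <= 0.8 * amp]
  # keep the contiguous run adjacent to the extremum (guards against
  # early artifacts re-entering the 20-80% corridor)
  if (length(sel) < 2L)
    return(list(slope_V_per_s = NA_real_, amplitude_mV = amp,
                t_extremum_s = (idx[ipk] - 1L) / sweep$fs))
  brk <- which(diff(sel) > 1L)
  if (length(brk) > 0L) sel <- sel[(max(brk) + 1L):length(sel)]
  # exact 20%/80% crossing times by linear interpolation, then a dense
  # resampled corridor: at 5 kHz only a handful of raw samples span the
  # rising limb and a line fitted to them is biased on a curved limb
  tt_limb <- (idx[limb] - 1L) / sweep$fs
  d_limb <- d[limb]
  cross_up <- function(level) {
    j <- which(d_limb >= level)[1L]  # first sample at/above the level
    if (is.na(j)) return(NA_real_)
    if (j == 1L || d_limb[j] == d_limb[j - 1L]) return(tt_limb[j])
    frac <- (level - d_limb[j - 1L]) / (d_limb[j] - d_limb[j - 1L])
    tt_limb[j - 1L] + frac * (tt_limb[j] - tt_limb[j - 1L])
  }
  t_lo <- cross_up(0.2 * amp)
  t_hi <- cross_up(0.8 * amp)
  if (is.na(t_lo) || is.na(t_hi))
    return(list(slope_V_per_s = NA_real_, amplitude_mV = amp,
                t_extremum_s = (idx[ipk] - 1L) / sweep$fs))
  if (!(t_hi > t_lo))
    return(list(slope_V_per_s = NA_real_, amplitude_mV = amp,
                t_extremum_s = (idx[ipk] - 1L) / sweep$fs))
  tg <- seq(t_lo, t_hi, length.out = 50L)
  yg <- stats::approx(tt_limb, x[idx][limb], xout = tg)$y
  fit <- stats::lm.fit(cbind(1, tg), yg)
  slope_mV_per_s <- fit$coefficients[[2L]]
  list(slope_V_per_s = slope_mV_per_s / 1000,
       amplitude_mV = amp,
       t_extremum_s = (idx[ipk] - 1L) / sweep$fs)
}

#' Fiber-volley amplitude
#'
#' Baseline-to-extremum amplitude within the fiber-volley window
#' (1.5-4 ms post-stimulus by default, after artifact blanking).
#'
#' @inheritParams fepsp_slope
#' @return Amplitude in mV (positive magnitude), or `NA_real_`.
#' @export
fiber_volley_amplitude <- function(sweep, stim_idx = 1L, polarity = -1,
                                   noise_floor_mV = 0.005) {
  stopifnot(inherits(sweep, "sweep"))
  w <- .evoked_windows()
  stim_t <- sweep$stim_times[stim_idx]
  base <- .sweep_baseline(sweep, sweep$stim_times[1L])
  idx <- .win_idx(sweep, stim_t, w$fv)
  if (length(idx) < 2L) return(NA_real_)
  d <- polarity * (sweep$samples[idx] - base)
  amp <- max(d)
  if (!is.finite(amp) || amp <= noise_floor_mV) NA_real_ else amp
}

#' Per-slice transmission rate
#'
#' Mean of per-sweep fEPSP slope / fiber-volley amplitude ratios; with the
#' slope in V/s and the FV in mV the ratio is in ms^-1. Sweeps with
#' non-positive or missing FV are excluded.
#'
#' @param slopes Numeric vector of fEPSP slopes (V/s).
#' @param fvs Numeric vector of fiber-volley amplitudes (mV), same length.
#' @return A list: `rate_per_ms` (mean ratio, magnitude), `n_used`,
#'   `n_excluded`.
#' @export
transmission_rate <- function(slopes, fvs) {
  if (length(slopes) != length(fvs)) stop("slopes and fvs differ in length")
  ok <- is.finite(slopes) & is.finite(fvs) & fvs > 0
  if (!any(ok)) return(list(rate_per_ms = NA_real_, n_used = 0L,
                            n_excluded = length(slopes)))
  list(rate_per_ms = mean(abs(slopes[ok]) / fvs[ok]),
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Paired-pulse ratio
#'
#' Slope of the second fEPSP divided by the slope of the first. At short
#' inter-stimulus intervals the decay of the first response is corrected
#' for by fitting a mono-exponential to its tail (from shortly after its
#' extremum to just before the second stimulus) and subtracting the
#' extrapolation before measuring the second slope.
#'
#' @param sweep A [evoked_sweep()] with exactly two stimuli.
#' @param polarity Response polarity as in [fepsp_slope()].
#' @return A list: `ppr`, `slope1_V_per_s`, `slope2_V_per_s`.
#' @export
paired_pulse_ratio <- function(sweep, polarity = -1) {
  stopifnot(inherits(sweep, "sweep"))
  if (length(sweep$stim_times) != 2L) stop("sweep must contain two stimuli")
  s1 <- fepsp_slope(sweep, 1L, polarity)
  if (is.na(s1$slope_V_per_s) || s1$slope_V_per_s == 0)
    return(list(ppr = NA_real_, slope1_V_per_s = s1$slope_V_per_s,
                slope2_V_per_s = NA_real_))
  fs <- sweep$fs
  base <- .sweep_baseline(sweep, sweep$stim_times[1L])
  corr <- NULL
  if (!is.na(s1$t_extremum_s)) {
    i_pk <- as.integer(round(s1$t_extremum_s * fs)) + 1L
    i_end <- as.integer(round((sweep$stim_times[2L] - 5e-4) * fs)) + 1L
    i_start <- i_pk + as.integer(round(2e-3 * fs))
    if (i_end - i_start >= 5L) {
      tt <- ((i_start:i_end) - 1L) / fs
      yy <- polarity * (sweep$samples[i_start:i_end] - base)
      if (all(yy > 0)) {
        fit <- stats::lm(log(yy) ~ tt)
        a <- exp(stats::coef(fit)[[1L]]); b <- stats::coef(fit)[[2L]]
        if (b < 0) {
          t_all <- (seq_along(sweep$samples) - 1L) / fs
          tail_pred <- polarity * a * exp(b * t_all)
          # only correct from the fit start onward
          tail_pred[t_all < tt[1L]] <- 0
          corr <- tail_pred
        }
      }
    }
  }
  s2 <- fepsp_slope(sweep, 2L, polarity, subtract = corr)
  list(ppr = if (is.na(s2$slope_V_per_s)) NA_real_ else
         s2$slope_V_per_s / s1$slope_V_per_s,
       slope1_V_per_s = s1$slope_V_per_s,
       slope2_V_per_s = s2$slope_V_per_s)
}

#' Input-output curve and slice-exclusion flag
#'
#' Assembles per-intensity fEPSP slope and fiber-volley amplitude, and
#' flags slices whose fEPSP amplitude stays below 1 mV at the maximum
#' (50 uA) stimulation strength.
#'
#' @param sweeps List of single-stimulus [evoked_sweep()]s with
#'   `stim_intensity_uA` set.
#' @param polarity Response polarity.
#' @param min_amp_mV,max_intensity_uA Exclusion rule parameters.
#' @return A list: `table` (data frame: intensity_uA, fv_amp_mV,
#'   slope_V_per_s, amplitude_mV), `excluded` (logical).
#' @export
io_curve <- function(sweeps, polarity = -1, min_amp_mV = 1,
                     max_intensity_uA = 50) {
  rows <- lapply(sweeps, function(sw) {
    m <- fepsp_slope(sw, 1L, polarity)
    data.frame(
      intensity_uA = sw$stim_intensity_uA,
      fv_amp_mV = fiber_volley_amplitude(sw, 1L, polarity),
      slope_V_per_s = m$slope_V_per_s,
      amplitude_mV = m$amplitude_mV
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$intensity_uA), , drop = FALSE]
  at_max <- tab$intensity_uA >= max_intensity_uA
  excluded <- any(at_max) &&
    all(is.na(tab$amplitude_mV[at_max]) | tab$amplitude_mV[at_max] < min_amp_mV)
  list(table = tab, excluded = excluded)
}
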