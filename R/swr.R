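#' Detect sharp-wave candidates in an LFP segment
#'
#' The raw trace is low-pass filtered at 45 Hz ([fft_filter()]); local
#' maxima exceeding `mean + 3 SD` of the full filtered segment are taken
#' as sharp-wave candidates, and maxima closer than 100 ms are merged,
#' keeping the larger. The SD is computed over the whole filtered segment,
#' events included (a robust median/MAD baseline is available via
#' `robust = TRUE`).
#'
#' @param seg A [recording()]; conventionally a 120 s artifact-free window.
#' @param cfg An [analysis_config()].
#' @param polarity `+1` for positive-going sharp waves (pyramidal-layer
#'   convention), `-1` for inverted recordings.
#' @param robust Use median + 3 x 1.4826 MAD instead of mean + 3 SD.
#' @return A list of class `"sw_candidates"`: `idx` (sample indices),
#'   `t_max` (s, absolute), `lp` (low-pass trace, mV), `baseline`,
#'   `threshold`, `fs`, `t0`, `duration_s`.
#' @export
detect_sharp_waves <- function(seg, cfg = analysis_config(),
                               polarity = 1, robust = FALSE) {
  stopifnot(is_recording(seg), polarity %in% c(-1, 1))
  lp <- polarity * fft_filter(seg$samples, seg$fs, 0, cfg$sw_lowpass_hz,
                              taper_hz = cfg$edge_taper_hz)
  if (robust) {
    base <- stats::median(lp)
    thr <- base + cfg$sw_sd_mult * stats::mad(lp)
  } else {
    base <- mean(lp)
    thr <- base + cfg$sw_sd_mult * stats::sd(lp)
  }
  cand <- local_maxima(lp)
  cand <- cand[lp[cand] > thr]
  # merge maxima closer than the minimum separation, keep the larger
  if (length(cand) > 1L) {
    min_sep <- cfg$sw_min_sep_ms / 1000 * seg$fs
    ord <- cand[order(lp[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  structure(
    list(idx = cand, t_max = seg$t0 + (cand - 1L) / seg$fs, lp = lp,
         baseline = base, threshold = thr, fs = seg$fs, t0 = seg$t0,
         duration_s = duration(seg)),
    class = "sw_candidates"
  )
}

#' Sharp-wave area under the curve
#'
#' Start and end of a sharp wave are the points where the low-pass trace
#' crosses the segment mean on either side of the event maximum; the area
#' is the trapezoidal integral of (trace - mean) between them, in mV·ms.
#'
#' @param sw A `sw_candidates` object ([detect_sharp_waves()]).
#' @param which_event Index into `sw$idx`.
#' @return A list: `area_mV_ms` (NA when a crossing falls outside the
#'   segment), `start_s`, `end_s`, `edge_clipped`.
#' @export
sw_area <- function(sw, which_event) {
  stopifnot(inherits(sw, "sw_candidates"))
  i <- sw$idx[which_event]
  x <- sw$lp - sw$baseline
  below <- x <= 0
  j0 <- i
  while (j0 > 1L && !below[j0]) j0 <- j0 - 1L
  j1 <- i
  n <- length(x)
  while (j1 < n && !below[j1]) j1 <- j1 + 1L
  if (!below[j0] || !below[j1]) {
    return(list(area_mV_ms = NA_real_, start_s = NA_real_, end_s = NA_real_,
                edge_clipped = TRUE))
  }
  # linear interpolation of the exact crossing points
  f0 <- x[j0 + 1L] / (x[j0 + 1L] - x[j0])      # fraction back from j0+1
  f1 <- x[j1 - 1L] / (x[j1 - 1L] - x[j1])      # fraction forward from j1-1
  dt_ms <- 1000 / sw$fs
  core <- (j0 + 1L):(j1 - 1L)
  area <- sum((x[core][-1] + x[core][-length(core)]) / 2) * dt_ms
  area <- area + x[j0 + 1L] * f0 / 2 * dt_ms + x[j1 - 1L] * f1 / 2 * dt_ms
  list(
    area_mV_ms = area,
    start_s = sw$t0 + (j0 + 1L - 1L - f0) / sw$fs,
    end_s = sw$t0 + (j1 - 1L - 1L + f1) / sw$fs,
    edge_clipped = FALSE
  )
}

#' Triple-point-minimax ripple amplitude and asymmetry
#'
#' For one ripple trough `m` flanked by local maxima `M1` (preceding) and
#' `M2` (following): amplitude is `mean(M1, M2) - m`; the rising component
#' is `M1 - m`, the falling `M2 - m`, and the ripple is included when the
#' normalized difference `|r - f| / max(r, f)` is below the asymmetry cap
#' (0.75).
#'
#' @param m1,m,m2 The three voltage points (mV).
#' @param asym_max Asymmetry cap.
#' @return A list: `amplitude_mV`, `asymmetry`, `included`.
#' @export
ripple_amplitude_tpm <- function(m1, m, m2, asym_max = 0.75) {
  r <- m1 - m
  f <- m2 - m
  if (r <= 0 || f <= 0)
    return(list(amplitude_mV = NA_real_, asymmetry = NA_real_,
                included = FALSE))
  asym <- abs(r - f) / max(r, f)
  list(amplitude_mV = (m1 + m2) / 2 - m, asymmetry = asym,
       included = asym < asym_max)
}

#' Extract and quantify ripples riding on one sharp wave
#'
#' A 125 ms window centred on the sharp-wave maximum is band-pass filtered
#' at 120-300 Hz; troughs within the stored sub-window (15 ms before to
#' 10 ms after the maximum) whose triple-point-minimax amplitude exceeds
#' `3 SD` of the band-passed window are kept, subject to the 75% asymmetry
#' rule. Ripple frequency is the mean reciprocal of consecutive included
#' trough intervals.
#'
#' @param seg The same [recording()] passed to [detect_sharp_waves()].
#' @param sw A `sw_candidates` object.
#' @param which_event Index into `sw$idx`.
#' @param cfg An [analysis_config()].
#' @return A list: `trough_times_s`, `amplitudes_mV`, `asymmetries`,
#'   `n_ripples`, `ripple_freq_hz` (NA with < 2 troughs), `skipped`
#'   (TRUE when the window does not fit in the segment).
#' @export
extract_ripples <- function(seg, sw, which_event, cfg = analysis_config()) {
  stopifnot(is_recording(seg), inherits(sw, "sw_candidates"))
  fs <- seg$fs
  i <- sw$idx[which_event]
  halfwin <- as.integer(round(cfg$ripple_win_ms / 2 / 1000 * fs))
  if (i - halfwin < 1L || i + halfwin > length(seg$samples)) {
    return(list(trough_times_s = numeric(0), amplitudes_mV = numeric(0),
                asymmetries = numeric(0), n_ripples = 0L,
                ripple_freq_hz = NA_real_, skipped = TRUE))
  }
  win <- seg$samples[(i - halfwin):(i + halfwin)]
  bp <- fft_filter(win - mean(win), fs, cfg$ripple_band[1],
                   cfg$ripple_band[2], taper_hz = 5)
  gate <- cfg$ripple_sd_mult * stats::sd(bp)
  ctr <- halfwin + 1L
  lo <- ctr - as.integer(round(0.015 * fs))
  hi <- ctr + as.integer(round(0.010 * fs))
  tr <- local_minima(bp)
  pk <- local_maxima(bp)
  tr <- tr[tr >= lo & tr <= hi]
  keep_t <- keep_a <- keep_y <- numeric(0)
  for (j in tr) {
    prev_pk <- pk[pk < j]
    next_pk <- pk[pk > j]
    if (length(prev_pk) == 0L || length(next_pk) == 0L) next
    m1 <- bp[max(prev_pk)]
    m2 <- bp[min(next_pk)]
    tpm <- ripple_amplitude_tpm(m1, bp[j], m2, cfg$ripple_asym_max)
    if (!tpm$included || is.na(tpm$amplitude_mV)) next
    if (tpm$amplitude_mV <= gate) next
    # sub-sample trough time by parabolic interpolation
    dj <- 0
    if (j > 1L && j < length(bp)) {
      den <- bp[j - 1L] - 2 * bp[j] + bp[j + 1L]
      if (den > 0) dj <- 0.5 * (bp[j - 1L] - bp[j + 1L]) / den
    }
    keep_t <- c(keep_t, seg$t0 + (i - halfwin + j - 2L + dj) / fs)
    keep_a <- c(keep_a, tpm$amplitude_mV)
    keep_y <- c(keep_y, tpm$asymmetry)
  }
  freq <- ripple_frequency(keep_t)
  list(trough_times_s = keep_t, amplitudes_mV = keep_a,
       asymmetries = keep_y, n_ripples = length(keep_t),
       ripple_freq_hz = freq, skipped = FALSE)
}

#' Mean ripple frequency from consecutive trough times
#'
#' Mean of the reciprocal intervals between the troughs of consecutive
#' included ripples within one sharp wave-ripple complex.
#'
#' @param trough_times_s Included ripple trough times (s), ascending.
#' @return Frequency in Hz, or `NA_real_` with fewer than two troughs.
#' @export
ripple_frequency <- function(trough_times_s) {
  if (length(trough_times_s) < 2L) return(NA_real_)
  mean(1 / diff(trough_times_s))
}

#' Full sharp wave-ripple analysis of a segment
#'
#' Runs [detect_sharp_waves()], then [sw_area()] and [extract_ripples()]
#' per event, and aggregates into the per-segment summary (incidence in
#' events/s, mean area, mean ripple amplitude and frequency).
#'
#' @param seg A [recording()].
#' @param cfg An [analysis_config()].
#' @param polarity Passed to [detect_sharp_waves()].
#' @return A list of class `"swr_result"`: `events` (data frame with one
#'   row per sharp wave: `t_max_s`, `sw_area_mV_ms`, `n_ripples`,
#'   `ripple_freq_hz`, `mean_ripple_amp_mV`), `summary` (list:
#'   `incidence_hz`, `mean_sw_area`, `mean_ripple_amp`,
#'   `mean_ripple_freq`, `n_events`, `duration_s`).
#' @export
analyze_swr <- function(seg, cfg = analysis_config(), polarity = 1) {
  sw <- detect_sharp_waves(seg, cfg, polarity)
  n <- length(sw$idx)
  rows <- lapply(seq_len(n), function(k) {
    ar <- sw_area(sw, k)
    rp <- extract_ripples(seg, sw, k, cfg)
    data.frame(
      t_max_s = sw$t_max[k],
      sw_area_mV_ms = ar$area_mV_ms,
      n_ripples = rp$n_ripples,
      ripple_freq_hz = rp$ripple_freq_hz,
      mean_ripple_amp_mV = if (rp$n_ripples > 0) mean(rp$amplitudes_mV)
                           else NA_real_
    )
  })
  events <- if (n > 0) do.call(rbind, rows) else
    data.frame(t_max_s = numeric(0), sw_area_mV_ms = numeric(0),
               n_ripples = integer(0), ripple_freq_hz = numeric(0),
               mean_ripple_amp_mV = numeric(0))
  structure(
    list(events = events,
         summary = swr_summary(events, sw$duration_s),
         candidates = sw),
    class = "swr_result"
  )
}

#' Per-segment sharp wave-ripple summary
#'
#' @param events Event data frame as produced by [analyze_swr()].
#' @param duration_s Segment duration in seconds.
#' @return A list: `incidence_hz` (`n/duration`), `mean_sw_area`,
#'   `mean_ripple_amp`, `mean_ripple_freq` (NA over empty sets),
#'   `n_events`, `duration_s`.
#' @export
swr_summary <- function(events, duration_s) {
  mean_or_na <- function(v) if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  n <- nrow(events)
  list(
    incidence_hz = n / duration_s,
    mean_sw_area = if (n) mean_or_na(events$sw_area_mV_ms) else NA_real_,
    mean_ripple_amp = if (n) mean_or_na(events$mean_ripple_amp_mV) else NA_real_,
    mean_ripple_freq = if (n) mean_or_na(events$ripple_freq_hz) else NA_real_,
    n_events = n, duration_s = duration_s
  )
}
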