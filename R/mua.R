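#' Instantaneous gamma phase of an LFP segment
#'
#' The trace is band-pass filtered at 15-45 Hz ([fft_filter()]) and the
#' analytic signal taken; the returned phase runs 0-360 degrees over each
#' gamma cycle with 0 deg at the filtered-trace trough (cycles run
#' trough-to-trough).
#'
#' @param seg A [recording()].
#' @param cfg An [analysis_config()] (band from `mua_gamma_band`).
#' @return A list of class `"phase_series"`: `phase_deg` in `[0, 360)` per
#'   sample, `amplitude_env` (mV), `filtered` (mV), `band`, `fs`, `t0`.
#' @export
gamma_phase <- function(seg, cfg = analysis_config()) {
  stopifnot(is_recording(seg))
  band <- cfg$mua_gamma_band
  if (duration(seg) < 5 / band[1])
    stop("segment must span several gamma cycles")
  filt <- fft_filter(seg$samples - mean(seg$samples), seg$fs,
                     band[1], band[2], taper_hz = cfg$edge_taper_hz)
  z <- analytic_signal(filt)
  # Arg = 0 at a filtered-trace peak; shift by 180 deg so troughs map to 0
  phase <- (Arg(z) * 180 / pi + 180) %% 360
  structure(
    list(phase_deg = phase, amplitude_env = Mod(z), filtered = filt,
         band = band, fs = seg$fs, t0 = seg$t0),
    class = "phase_series"
  )
}

#' Detect multi-unit spikes in the high-frequency LFP component
#'
#' The trace is band-pass filtered at 500-3000 Hz (top edge clipped to
#' 0.9 x Nyquist when the sampling rate cannot support 3000 Hz, i.e.
#' 2250 Hz at 5 kHz), wavelet-denoised ([wavelet_denoise()]), and local
#' extrema of the absolute denoised trace exceeding the 0.0125 mV floor
#' are collected with a 1 ms refractory period (the larger event wins).
#' Further evaluation uses the gated subset: events whose amplitude lies
#' in the upper quartile of all detected amplitudes (ties at the boundary
#' included).
#'
#' @param seg A [recording()].
#' @param cfg An [analysis_config()].
#' @param snippet_ms Half-width of the stored waveform snippet (ms).
#' @return A list of class `"unit_events"`: `times` (s, absolute),
#'   `amplitudes` (mV), `gated` (logical), `waveforms` (matrix, one row
#'   per event, mV), `fs`, `snippet_ms`. Zero detections give empty
#'   vectors (valid).
#' @export
detect_units <- function(seg, cfg = analysis_config(), snippet_ms = 2) {
  stopifnot(is_recording(seg))
  fs <- seg$fs
  hi <- min(cfg$unit_band[2], 0.9 * fs / 2)
  filt <- fft_filter(seg$samples - mean(seg$samples), fs,
                     cfg$unit_band[1], hi, taper_hz = 50)
  den <- wavelet_denoise(filt)
  a <- abs(den)
  cand <- local_maxima(a)
  cand <- cand[a[cand] > cfg$unit_amp_floor_mV]
  empty <- function() structure(
    list(times = numeric(0), amplitudes = numeric(0), gated = logical(0),
         waveforms = matrix(numeric(0), 0, 0), fs = fs,
         snippet_ms = snippet_ms),
    class = "unit_events")
  if (length(cand) == 0L) return(empty())
  # 1 ms refractory period, larger amplitude wins
  refr <- as.integer(round(fs / 1000))
  ord <- cand[order(a[cand], decreasing = TRUE)]
  keep <- logical(length(a))
  taken <- logical(length(a))
  for (i in ord) {
    win <- max(1L, i - refr):min(length(a), i + refr)
    if (!any(taken[win])) {
      keep[i] <- TRUE
      taken[win] <- TRUE
    }
  }
  idx <- sort(which(keep))
  amps <- a[idx]
  q3 <- stats::quantile(amps, 0.75, names = FALSE)
  hw <- as.integer(round(snippet_ms / 1000 * fs))
  wf <- t(vapply(idx, function(i) {
    lo <- i - hw; hi2 <- i + hw
    out <- rep(NA_real_, 2L * hw + 1L)
    src <- max(1L, lo):min(length(den), hi2)
    out[src - lo + 1L] <- den[src]
    out
  }, numeric(2L * hw + 1L)))
  structure(
    list(times = seg$t0 + (idx - 1L) / fs, amplitudes = amps,
         gated = amps >= q3, waveforms = wf, fs = fs,
         snippet_ms = snippet_ms),
    class = "unit_events"
  )
}

#' Gamma-phase firing-probability profile of detected units
#'
#' Bins the gamma phases at which the gated units fire into `n_bins`
#' equal bins of `[0, 360)` and normalizes to a probability distribution;
#' the activation curve is its cumulative sum from 0 deg (ending at 1).
#'
#' @param units A `unit_events` object ([detect_units()]).
#' @param phases A `phase_series` ([gamma_phase()]) from the same segment.
#' @param n_bins Number of phase bins (default 20, i.e. 18 deg bins).
#' @return A list of class `"phase_profile"`: `bin_centers_deg`,
#'   `firing_prob` (sums to 1), `activation` (monotone, ends at 1),
#'   `n_units`.
#' @export
phase_profile <- function(units, phases, n_bins = 20L) {
  stopifnot(inherits(units, "unit_events"), inherits(phases, "phase_series"))
  tg <- units$times[units$gated]
  if (length(tg) == 0L) stop("no units to bin")
  idx <- as.integer(round((tg - phases$t0) * phases$fs)) + 1L
  idx <- idx[idx >= 1L & idx <= length(phases$phase_deg)]
  if (length(idx) == 0L) stop("no units to bin")
  ph <- phases$phase_deg[idx]
  edges <- seq(0, 360, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(ph, edges), n_bins), nbins = n_bins)
  prob <- counts / sum(counts)
  structure(
    list(bin_centers_deg = edges[-length(edges)] + diff(edges) / 2,
         firing_prob = prob, activation = cumsum(prob),
         n_units = length(idx)),
    class = "phase_profile"
  )
}

#' Average gamma cycle waveform
#'
#' Cuts the band-passed trace into trough-to-trough cycles (phase wraps of
#' the [gamma_phase()] series), resamples each cycle to 360 points by
#' linear interpolation and averages them, giving the mean cycle waveform
#' against phase in degrees.
#'
#' @param phases A `phase_series`.
#' @param min_cycles Minimum number of complete cycles required.
#' @return A list: `phase_deg` (0..359), `amplitude_mV` (mean waveform),
#'   `n_cycles`.
#' @export
average_gamma_cycle <- function(phases, min_cycles = 10L) {
  stopifnot(inherits(phases, "phase_series"))
  wraps <- which(diff(phases$phase_deg) < -180) + 1L  # cycle starts (troughs)
  if (length(wraps) < min_cycles + 1L)
    stop("need at least ", min_cycles, " complete gamma cycles")
  grid <- seq(0, 1, length.out = 361L)[1:360]
  acc <- numeric(360)
  nc <- 0L
  for (k in seq_len(length(wraps) - 1L)) {
    i0 <- wraps[k]; i1 <- wraps[k + 1L] - 1L
    if (i1 - i0 < 3L) next
    seg <- phases$filtered[i0:i1]
    u <- seq(0, 1, length.out = length(seg))
    acc <- acc + stats::approx(u, seg, xout = grid)$y
    nc <- nc + 1L
  }
  list(phase_deg = 0:359, amplitude_mV = acc / nc, n_cycles = nc)
}

#' Waveform features of the detected unit spikes
#'
#' Per gated event: height (baseline-to-extremum of the stored snippet,
#' baseline estimated from the snippet edges), width at half height
#' (linear-interpolated crossings around the central extremum), and their
#' ratio. Events whose half-height crossings are clipped by the snippet
#' edge are excluded from the width/ratio summaries but still counted.
#'
#' @param units A `unit_events` object with stored waveforms.
#' @return A list of class `"spike_features"`: `height_mV`,
#'   `width_at_half_height_ms`, `height_to_width_ratio` (mV/ms; means over
#'   usable gated events), `n_spikes_in_window` (all detections),
#'   `per_event` data frame.
#' @export
spike_waveform_features <- function(units) {
  stopifnot(inherits(units, "unit_events"))
  gi <- which(units$gated)
  if (length(gi) == 0L) stop("no gated units with stored waveforms")
  fs <- units$fs
  nw <- ncol(units$waveforms)
  ctr <- (nw + 1L) %/% 2L
  nedge <- max(1L, as.integer(round(0.2 * fs / 1000)))  # ~0.2 ms of edge
  res <- lapply(gi, function(i) {
    w <- units$waveforms[i, ]
    if (anyNA(w)) return(data.frame(height = NA_real_, width = NA_real_))
    base <- mean(c(w[seq_len(nedge)], w[seq(nw - nedge + 1L, nw)]))
    d <- abs(w - base)
    h <- d[ctr]
    half <- h / 2
    cross_from <- function(dir) {
      j <- ctr + dir
      while (j >= 1L && j <= nw) {
        if (d[j] < half) {
          inner <- j - dir
          frac <- (d[inner] - half) / (d[inner] - d[j])
          return(abs(inner - ctr) + frac)
        }
        j <- j + dir
      }
      NA_real_
    }
    l <- cross_from(-1L); r <- cross_from(1L)
    width_ms <- if (is.na(l) || is.na(r)) NA_real_ else (l + r) / fs * 1000
    data.frame(height = h, width = width_ms)
  })
  per <- do.call(rbind, res)
  per$ratio <- per$height / per$width
  ok <- stats::complete.cases(per)
  structure(
    list(height_mV = mean(per$height, na.rm = TRUE),
         width_at_half_height_ms = mean(per$width[ok]),
         height_to_width_ratio = mean(per$ratio[ok]),
         n_spikes_in_window = length(units$times),
         per_event = per),
    class = "spike_features"
  )
}
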