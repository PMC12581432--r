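#' Evaluate an expression with a local RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of (config, seed) and never
#' leak global RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# von Mises sampler, Best-Fisher (1979) rejection; radians.
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu) %% (2 * pi)
    }
  }
  out
}

# 1/f^exponent background noise, SD = sd_out. The spectrum is flat below
# f_floor_hz, emulating the AC coupling of extracellular amplifiers that
# removes very slow drift; all band metrics ignore this region anyway.
.colored_noise <- function(n, fs, exponent, sd_out, f_floor_hz = 2) {
  if (sd_out <= 0) return(numeric(n))
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * fs / n
  shape <- 1 / pmax(f, f_floor_hz)^(exponent / 2)
  shape[1] <- 0
  z <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(z) * shape, inverse = TRUE)) / n
  x * sd_out / stats::sd(x)
}

#' Configuration for the synthetic gamma-LFP generator
#'
#' Defaults emulate a carbachol-type in vitro gamma regime: 40 Hz peak on
#' a 1/f background, two-minute segment at 5 kHz, oscillation amplitude
#' chosen so the integrated 20-80 Hz power is of order 10^3 uV^2 (log
#' power ~ 3.2), and an autocorrelation decay constant of 30 ms, in the
#' middle of the published 13-32 ms range.
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Segment length (s).
#' @param peak_f_hz Oscillation frequency, inside (20, 80).
#' @param amplitude_uV Oscillation amplitude (uV).
#' @param decay_tau_ms Target autocorrelogram decay constant (ms); sets
#'   the cycle-to-cycle period jitter unless `phase_jitter` is given.
#' @param phase_jitter Cycle-to-cycle period SD as a fraction of the
#'   period; overrides `decay_tau_ms` when non-NULL.
#' @param envelope_cv Coefficient of variation of the slow amplitude
#'   envelope (Ornstein-Uhlenbeck, 200 ms correlation time).
#' @param noise_exponent 1/f slope of the background.
#' @param noise_uV Background SD (uV).
#' @param seed Integer seed.
#' @return A list of class `"gamma_sim_config"`.
#' @export
gamma_sim_config <- function(fs = 5000, duration_s = 120, peak_f_hz = 40,
                             amplitude_uV = 60, decay_tau_ms = 30,
                             phase_jitter = NULL, envelope_cv = 0.1,
                             noise_exponent = 2, noise_uV = 20, seed = 1L) {
  if (peak_f_hz <= 20 || peak_f_hz >= 80)
    stop("peak_f_hz must lie inside (20, 80)")
  stopifnot(fs > 0, duration_s > 0, amplitude_uV >= 0, noise_uV >= 0)
  structure(as.list(environment()), class = "gamma_sim_config")
}

#' Generate a synthetic gamma-oscillation LFP with ground truth
#'
#' Phase-diffusion synthesis: the oscillation is `-amplitude * cos(phi)`
#' where `phi` performs a random walk around the mean angular velocity
#' `2 pi peak_f`, so the ground-truth phase of every sample is exact and
#' the autocorrelation envelope is exactly exponential,
#' `exp(-lag/tau) * cos(2 pi f0 lag)`, with
#' `tau = 2 / ((2 pi j)^2 f0)` for an equivalent cycle-to-cycle period SD
#' fraction `j`. A slow amplitude envelope and a 1/f background are added
#' on top.
#'
#' @param cfg A [gamma_sim_config()].
#' @return A list: `rec` ([recording()], mV), `truth` (list: `peak_f_hz`,
#'   `band_power_uV2` (expected 20-80 Hz power), `decay_tau_ms`,
#'   `phase_jitter`, `phase_deg` per sample, `cycle_starts_s`).
#' @export
gen_gamma_lfp <- function(cfg = gamma_sim_config()) {
  stopifnot(inherits(cfg, "gamma_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    n <- as.integer(round(cfg$duration_s * fs))
    f0 <- cfg$peak_f_hz
    T0 <- 1 / f0
    j <- if (!is.null(cfg$phase_jitter)) cfg$phase_jitter else
      sqrt(2 / (cfg$decay_tau_ms / 1000 * f0)) / (2 * pi)
    tau_eff <- 2 / ((2 * pi * j)^2 * f0) * 1000
    # per-sample phase random walk: increments sigma * sqrt(dt) with
    # sigma^2 = 2 / tau give the exact autocorrelation envelope
    # exp(-lag / tau) * cos(2 pi f0 lag); j is the equivalent
    # cycle-to-cycle period SD fraction
    sigma <- 2 * pi * j * sqrt(f0)
    t <- (0:(n - 1)) / fs
    # band-limit the phase-increment noise to ~250 Hz (2 ms moving
    # average, DC gain 1): the long-lag diffusion constant — and hence
    # the autocorrelation decay tau — is untouched, but the waveform no
    # longer carries unphysical sample-scale clicks that would bleed
    # into the 500-2250 Hz unit band
    w <- max(1L, as.integer(round(fs * 0.002)))
    z <- stats::rnorm(n + w)
    z <- as.numeric(stats::filter(z, rep(1 / w, w), sides = 2L))
    z <- z[!is.na(z)][seq_len(n)]
    dphi <- 2 * pi * f0 / fs + sigma * sqrt(1 / fs) * z
    unwrapped <- cumsum(dphi) - dphi[1L]
    # cycle starts: first-passage times of the phase through multiples of
    # 2 pi (cummax makes first passage well defined when the walk dips)
    mono <- cummax(unwrapped)
    kmax <- floor(mono[n] / (2 * pi))
    bounds <- stats::approx(mono, t, xout = 2 * pi * (0:kmax),
                            ties = min)$y
    phase <- unwrapped %% (2 * pi)
    # slow OU amplitude envelope, mean 1
    env <- 1
    if (cfg$envelope_cv > 0) {
      tau_env <- 0.2
      a <- exp(-1 / (fs * tau_env))
      e <- stats::filter(stats::rnorm(n) * sqrt(1 - a^2), a,
                         method = "recursive")
      env <- 1 + cfg$envelope_cv * as.numeric(e)
      env <- pmax(env, 0)
    }
    osc_uV <- -cfg$amplitude_uV * env * cos(phase)  # trough at phase 0
    noise_uV <- .colored_noise(n, fs, cfg$noise_exponent, cfg$noise_uV)
    samples_mV <- (osc_uV + noise_uV) / 1000
    # the phase diffusion gives a Lorentzian line of HWHM 1/(2 pi tau);
    # part of the oscillation power falls outside the 20-80 Hz band
    gam <- 1 / (2 * pi * tau_eff / 1000)
    inband <- (atan((f0 - 20) / gam) + atan((80 - f0) / gam)) / pi
    list(
      rec = recording(samples_mV, fs, label = "synthetic gamma"),
      truth = list(
        peak_f_hz = f0,
        band_power_uV2 = cfg$amplitude_uV^2 / 2 * (1 + cfg$envelope_cv^2) *
          inband,
        decay_tau_ms = tau_eff,
        phase_jitter = j,
        phase_deg = phase * 180 / pi,
        phase_unwrapped_rad = unwrapped,
        cycle_starts_s = bounds[bounds <= cfg$duration_s]
      )
    )
  })
}

#' Configuration for phase-locked synthetic unit activity
#'
#' @param rate_hz Mean unit firing rate (Hz).
#' @param pref_phase_deg Preferred gamma phase (deg, trough = 0).
#' @param kappa von Mises concentration (0 = uniform).
#' @param height_mV,half_width_ms Spike template peak height and width at
#'   half height.
#' @param height_cv Lognormal coefficient of variation of per-spike
#'   heights, emulating the amplitude spread of units at different
#'   distances from the electrode (0 = identical templates). Upper
#'   quartile gating is only meaningful when this spread dominates
#'   measurement noise, as it does in recordings.
#' @param seed Integer seed.
#' @return A list of class `"unit_sim_config"`.
#' @export
unit_sim_config <- function(rate_hz = 5, pref_phase_deg = 270, kappa = 2,
                            height_mV = 0.05, half_width_ms = 0.4,
                            height_cv = 0.4, seed = 1L) {
  stopifnot(rate_hz > 0, kappa >= 0, height_mV > 0, half_width_ms > 0,
            height_cv >= 0)
  structure(as.list(environment()), class = "unit_sim_config")
}

# Ricker (Mexican-hat) spike template: bandpass-friendly biphasic shape
# with unit peak height; `half_width_ms` is its width at half height.
.spike_template <- function(fs, half_width_ms) {
  # Ricker (1 - u^2) exp(-u^2/2) falls to 1/2 at |u| ~ 0.9665
  sigma_s <- half_width_ms / 1000 / (2 * 0.9665)
  hw <- as.integer(round(4 * sigma_s * fs))
  u <- ((-hw):hw) / fs / sigma_s
  (1 - u^2) * exp(-u^2 / 2)
}

#' Add phase-locked spikes to a synthetic gamma LFP
#'
#' Spike count is Poisson with the configured rate; each spike draws a
#' gamma phase from a von Mises density and is placed at that phase
#' fraction of a uniformly chosen cycle, then a negative-going biphasic
#' template is added to the trace.
#'
#' @param lfp Output of [gen_gamma_lfp()].
#' @param cfg A [unit_sim_config()].
#' @return A list: `rec` (recording with spikes added), `truth` (list:
#'   `times_s` sample-aligned spike centres, `phases_deg` the generator
#'   phase realized at those samples, `drawn_phases_deg` the von Mises
#'   draws, `n_spikes`, template parameters).
#' @export
gen_locked_units <- function(lfp, cfg = unit_sim_config()) {
  stopifnot(inherits(cfg, "unit_sim_config"))
  with_seed(cfg$seed, {
    rec <- lfp$rec
    fs <- rec$fs
    dur <- duration(rec)
    bounds <- lfp$truth$cycle_starts_s
    n_cyc <- length(bounds) - 1L
    n_spk <- stats::rpois(1, cfg$rate_hz * dur)
    cyc <- sample.int(n_cyc, n_spk, replace = TRUE)
    th <- .rvonmises(n_spk, cfg$pref_phase_deg * pi / 180, cfg$kappa)
    # place each spike at the sample of the chosen cycle whose realized
    # phase is closest (circularly) to the drawn angle, so the realized
    # phase distribution matches the drawn von Mises distribution
    phase_rad <- lfp$truth$phase_deg * pi / 180
    i0 <- as.integer(round(bounds * fs)) + 1L
    tt <- vapply(seq_len(n_spk), function(s) {
      rng <- i0[cyc[s]]:(i0[cyc[s] + 1L] - 1L)
      dd <- abs((phase_rad[rng] - th[s] + pi) %% (2 * pi) - pi)
      (rng[which.min(dd)] - 1L) / fs
    }, numeric(1))
    ok <- tt < dur - 0.005 & tt > 0.005
    tt <- tt[ok]; th <- th[ok]
    ord <- order(tt)
    tt <- tt[ord]; th <- th[ord]
    tmpl <- -.spike_template(fs, cfg$half_width_ms)
    hw <- (length(tmpl) - 1L) %/% 2L
    # lognormal per-spike heights with mean height_mV and CV height_cv
    heights <- if (cfg$height_cv > 0) {
      sl <- sqrt(log(1 + cfg$height_cv^2))
      cfg$height_mV * exp(stats::rnorm(length(tt), -sl^2 / 2, sl))
    } else rep(cfg$height_mV, length(tt))
    x <- rec$samples
    idx <- as.integer(round(tt * fs)) + 1L
    for (k in seq_along(idx)) {
      i <- idx[k]
      x[(i - hw):(i + hw)] <- x[(i - hw):(i + hw)] + heights[k] * tmpl
    }
    # truth times are the realized (sample-aligned) template centres and
    # truth phases the generator's own phase at those samples
    tt <- (idx - 1L) / fs
    list(
      rec = recording(x, fs, t0 = rec$t0, label = "synthetic gamma + units"),
      truth = list(times_s = tt,
                   phases_deg = lfp$truth$phase_deg[idx],
                   drawn_phases_deg = th * 180 / pi,
                   heights_mV = heights,
                   n_spikes = length(tt), height_mV = cfg$height_mV,
                   half_width_ms = cfg$half_width_ms)
    )
  })
}

#' Configuration for the synthetic sharp wave-ripple generator
#'
#' Defaults give sharp waves whose amplitude is six times the SD of the
#' low-frequency background (the regime in which the detector is
#' benchmarked), with 200 Hz ripple bursts riding on each event.
#'
#' @param fs,duration_s Sampling rate (Hz) and segment length (s).
#' @param incidence_hz Mean event rate (Hz); events are Poisson with an
#'   enforced 200 ms minimum separation.
#' @param sw_amp_mV,sw_sigma_ms Gaussian sharp-wave peak amplitude and
#'   time SD.
#' @param ripple_f_hz,ripple_cycles,ripple_amp_mV Ripple tone burst:
#'   frequency inside (120, 300), cycle count, amplitude.
#' @param noise_mV Background SD (mV).
#' @param noise_exponent 1/f slope of the background (2 approximates the
#'   low-frequency-dominated spectrum of quiescent slice LFP).
#' @param seed Integer seed.
#' @return A list of class `"swr_sim_config"`.
#' @export
swr_sim_config <- function(fs = 5000, duration_s = 120, incidence_hz = 0.5,
                           sw_amp_mV = 0.2, sw_sigma_ms = 10,
                           ripple_f_hz = 200, ripple_cycles = 5,
                           ripple_amp_mV = 0.05, noise_mV = 0.2 / 6,
                           noise_exponent = 2, seed = 1L) {
  stopifnot(incidence_hz >= 0, fs > 0, duration_s > 0, sw_amp_mV >= 0,
            sw_sigma_ms > 0, ripple_cycles > 0, ripple_amp_mV >= 0,
            noise_mV >= 0)
  if (ripple_f_hz <= 120 || ripple_f_hz >= 300)
    stop("ripple_f_hz must lie inside (120, 300)")
  structure(as.list(environment()), class = "swr_sim_config")
}

#' Generate a synthetic sharp wave-ripple train with ground truth
#'
#' Event times are Poisson with a 200 ms minimum separation; each event is
#' a Gaussian sharp-wave transient with a Hann-windowed ripple tone burst
#' centred on its maximum, on a 1/f^2 background.
#'
#' @param cfg A [swr_sim_config()].
#' @return A list: `rec` ([recording()]), `truth` (list: `times_s`,
#'   `n_events`, `sw_area_mV_ms` (analytic full-integral area
#'   `amp * sigma * sqrt(2 pi)`), `ripple_f_hz`, `incidence_hz` realized).
#' @export
gen_swr_train <- function(cfg = swr_sim_config()) {
  stopifnot(inherits(cfg, "swr_sim_config"))
  with_seed(cfg$seed, {
    fs <- cfg$fs
    n <- as.integer(round(cfg$duration_s * fs))
    t <- (0:(n - 1)) / fs
    x <- .colored_noise(n, fs, cfg$noise_exponent, cfg$noise_mV)
    margin <- 0.1
    times <- numeric(0)
    if (cfg$incidence_hz > 0) {
      n_ev <- stats::rpois(1, cfg$incidence_hz * cfg$duration_s)
      cand <- sort(stats::runif(n_ev, margin, cfg$duration_s - margin))
      for (tc in cand) {
        if (length(times) == 0L || tc - times[length(times)] >= 0.2)
          times <- c(times, tc)
      }
    }
    sigma_s <- cfg$sw_sigma_ms / 1000
    rip_dur <- cfg$ripple_cycles / cfg$ripple_f_hz
    for (tc in times) {
      sel <- which(abs(t - tc) < 5 * sigma_s)
      x[sel] <- x[sel] + cfg$sw_amp_mV * exp(-(t[sel] - tc)^2 / (2 * sigma_s^2))
      rsel <- which(abs(t - tc) < rip_dur / 2)
      u <- abs(t[rsel] - tc) / (rip_dur / 2)  # 0 .. 1
      # Tukey (flat-core) envelope: tapered outer half, flat centre, so
      # inter-trough intervals in the core carry the nominal frequency
      env <- ifelse(u <= 0.5, 1, 0.5 + 0.5 * cos(pi * (u - 0.5) / 0.5))
      x[rsel] <- x[rsel] + cfg$ripple_amp_mV * env *
        cos(2 * pi * cfg$ripple_f_hz * (t[rsel] - tc))
    }
    list(
      rec = recording(x, fs, label = "synthetic SW-R"),
      truth = list(
        times_s = times, n_events = length(times),
        sw_area_mV_ms = cfg$sw_amp_mV * sigma_s * sqrt(2 * pi) * 1000,
        ripple_f_hz = cfg$ripple_f_hz,
        incidence_hz = length(times) / cfg$duration_s
      )
    )
  })
}

#' Configuration for the synthetic evoked-fEPSP generator
#'
#' Emulates an input-output protocol (10-50 uA) and paired-pulse
#' protocols (10-500 ms intervals) at the Schaffer collateral-CA1
#' synapse: stimulus artifact, fiber volley and a difference-of-
#' exponentials fEPSP whose amplitudes scale linearly with intensity.
#'
#' @param fs Sampling rate (Hz).
#' @param intensities_uA Stimulation intensities for the I-O protocol.
#' @param fv_gain_mV_per_uA,fepsp_gain_mV_per_uA Linear amplitude gains.
#' @param tau_rise_ms,tau_decay_ms fEPSP kinetics.
#' @param onset_ms fEPSP onset latency after the stimulus.
#' @param noise_mV Additive white noise SD.
#' @param pp_intervals_ms Paired-pulse inter-stimulus intervals.
#' @param pp_facilitation Facilitation ratio (true PPR) per interval.
#' @param seed Integer seed.
#' @return A list of class `"fepsp_sim_config"`.
#' @export
fepsp_sim_config <- function(fs = 5000,
                             intensities_uA = seq(10, 50, by = 10),
                             fv_gain_mV_per_uA = 0.008,
                             fepsp_gain_mV_per_uA = 0.04,
                             tau_rise_ms = 1, tau_decay_ms = 6,
                             onset_ms = 4.5, noise_mV = 0.003,
                             pp_intervals_ms = c(10, 25, 50, 100, 250, 500),
                             pp_facilitation = c(1.6, 1.7, 1.5, 1.3, 1.1, 1.05),
                             seed = 1L) {
  stopifnot(fv_gain_mV_per_uA >= 0, fepsp_gain_mV_per_uA >= 0,
            tau_rise_ms > 0, tau_decay_ms > tau_rise_ms,
            length(pp_intervals_ms) == length(pp_facilitation))
  structure(as.list(environment()), class = "fepsp_sim_config")
}

# Normalized difference-of-exponentials fEPSP shape, peak 1 at t_pk.
.fepsp_shape <- function(t_s, tau_r, tau_d) {
  s <- ifelse(t_s <= 0, 0, exp(-t_s / tau_d) - exp(-t_s / tau_r))
  t_pk <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  s / (exp(-t_pk / tau_d) - exp(-t_pk / tau_r))
}

# One synthetic sweep; stims at `stim_times` s, per-stim fEPSP amplitude
# `amps_mV` (positive magnitudes; responses are negative-going).
.make_sweep <- function(cfg, stim_times, intensity_uA, amps_mV) {
  fs <- cfg$fs
  dur <- max(stim_times) + 0.08
  n <- as.integer(round(dur * fs))
  t <- (0:(n - 1)) / fs
  x <- stats::rnorm(n, 0, cfg$noise_mV)
  tau_r <- cfg$tau_rise_ms / 1000
  tau_d <- cfg$tau_decay_ms / 1000
  for (k in seq_along(stim_times)) {
    ts <- t - stim_times[k]
    # biphasic stimulus artifact, 0.6 ms, strictly causal
    x <- x + (ts >= 0) * (2 * exp(-(ts - 2e-4)^2 / (2 * (1e-4)^2)) -
                            1.5 * exp(-(ts - 5e-4)^2 / (2 * (1e-4)^2)))
    # fiber volley: fast negative deflection at 2.2 ms
    x <- x - cfg$fv_gain_mV_per_uA * intensity_uA *
      exp(-(ts - 2.2e-3)^2 / (2 * (2.5e-4)^2))
    # fEPSP
    x <- x - amps_mV[k] * .fepsp_shape(ts - cfg$onset_ms / 1000, tau_r, tau_d)
  }
  evoked_sweep(x, fs, stim_times, intensity_uA)
}

#' Generate synthetic evoked-response sweeps with ground truth
#'
#' Produces one single-stimulus sweep per intensity (input-output
#' protocol) and one two-stimulus sweep per paired-pulse interval at the
#' maximum intensity.
#'
#' @param cfg A [fepsp_sim_config()].
#' @return A list: `io_sweeps` (list of [evoked_sweep()]),
#'   `pp_sweeps` (list), `truth` (list: `fv_amp_mV`, `fepsp_amp_mV` per
#'   intensity, `ppr` per interval, kinetics and windows).
#' @export
gen_fepsp_sweeps <- function(cfg = fepsp_sim_config()) {
  stopifnot(inherits(cfg, "fepsp_sim_config"))
  with_seed(cfg$seed, {
    amps <- cfg$fepsp_gain_mV_per_uA * cfg$intensities_uA
    io <- lapply(seq_along(cfg$intensities_uA), function(i) {
      .make_sweep(cfg, 0.02, cfg$intensities_uA[i], amps[i])
    })
    imax <- max(cfg$intensities_uA)
    amax <- cfg$fepsp_gain_mV_per_uA * imax
    pp <- lapply(seq_along(cfg$pp_intervals_ms), function(i) {
      isi <- cfg$pp_intervals_ms[i] / 1000
      .make_sweep(cfg, c(0.02, 0.02 + isi), imax,
                  c(amax, amax * cfg$pp_facilitation[i]))
    })
    list(
      io_sweeps = io, pp_sweeps = pp,
      truth = list(
        intensities_uA = cfg$intensities_uA,
        fv_amp_mV = cfg$fv_gain_mV_per_uA * cfg$intensities_uA,
        fepsp_amp_mV = amps,
        pp_intervals_ms = cfg$pp_intervals_ms,
        ppr = cfg$pp_facilitation,
        tau_rise_ms = cfg$tau_rise_ms, tau_decay_ms = cfg$tau_decay_ms,
        onset_ms = cfg$onset_ms
      )
    )
  })
}
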