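test_that("phase of a pure tone advances linearly and is 0 at troughs", {
  rec <- sine_recording(f = 40, amp_mV = 0.1, dur = 10)
  ph <- gamma_phase(rec)
  # unwrapped phase advances 40 * 360 deg per second
  dphi <- diff(ph$phase_deg) %% 360
  core <- 5000:45000  # avoid filter edges
  expect_equal(mean(dphi[core]) * rec$fs, 40 * 360, tolerance = 1e-3)
  mins <- which(diff(sign(diff(ph$filtered))) > 0) + 1L
  mins <- mins[mins > 5000 & mins < 45000]
  dev <- ph$phase_deg[mins]
  dev <- pmin(dev, 360 - dev)
  expect_lt(max(dev), 2)
})

test_that("unit detection recalls injected template spikes", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 20, seed = 11))
  u <- gen_locked_units(g, unit_sim_config(rate_hz = 2.5, kappa = 2,
                                           height_cv = 0, seed = 12))
  ev <- detect_units(u$rec)
  m <- match_events(ev$times, u$truth$times_s, tol = 4e-4)
  expect_gte(m$tp / m$n_truth, 0.98)
  expect_true(all(diff(ev$times) > 0))
  expect_true(all(ev$amplitudes > 0))
})

test_that("spikes below the 0.0125 mV floor are not detected", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 20, seed = 13))
  u <- gen_locked_units(g, unit_sim_config(rate_hz = 2.5, height_mV = 0.010,
                                           height_cv = 0, seed = 14))
  ev <- detect_units(u$rec)
  m <- match_events(ev$times, u$truth$times_s, tol = 4e-4)
  expect_lte(m$tp / m$n_truth, 0.05)
})

test_that("upper-quartile gating keeps exactly a quarter of detections", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 60, seed = 15))
  u <- gen_locked_units(g, unit_sim_config(rate_hz = 5, seed = 16))
  ev <- detect_units(u$rec)
  n <- length(ev$amplitudes)
  expect_equal(sum(ev$gated), ceiling(n / 4), tolerance = 1,
               ignore_attr = TRUE)
  expect_true(all(ev$amplitudes[ev$gated] >=
                    stats::quantile(ev$amplitudes, 0.75, names = FALSE)))
})

test_that("phase profile is a probability distribution with monotone
           activation for arbitrary spike sets", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 30, seed = 21))
  ph <- gamma_phase(g$rec)
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:500, 1)
    times <- sort(runif(n, 0.1, 29.9))
    units <- structure(
      list(times = times, amplitudes = rep(0.05, n),
           gated = rep(TRUE, n), waveforms = matrix(0, n, 21), fs = 5000,
           snippet_ms = 2),
      class = "unit_events")
    pr <- phase_profile(units, ph)
    expect_equal(sum(pr$firing_prob), 1, tolerance = 1e-9)
    expect_true(all(diff(pr$activation) >= -1e-12))
    expect_equal(pr$activation[length(pr$activation)], 1, tolerance = 1e-9)
  }
})

test_that("phase preference is recovered and sharpens with kappa", {
  means <- res <- numeric(0)
  for (k in c(0.5, 2)) {
    g <- gen_gamma_lfp(gamma_sim_config(seed = 31))
    u <- gen_locked_units(g, unit_sim_config(rate_hz = 30, kappa = k,
                                             pref_phase_deg = 270,
                                             seed = 32))
    pr <- phase_profile(detect_units(u$rec), gamma_phase(u$rec))
    means <- c(means, profile_circ_mean(pr))
    res <- c(res, profile_resultant(pr))
  }
  for (m in means) {
    d <- abs(m - 270)
    expect_lte(min(d, 360 - d), 15)
  }
  expect_true(all(diff(res) > 0))
})

test_that("kappa = 0 gives a flat profile", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 120, seed = 33))
  u <- gen_locked_units(g, unit_sim_config(rate_hz = 30, kappa = 0,
                                           seed = 34))
  pr <- phase_profile(detect_units(u$rec), gamma_phase(u$rec))
  se <- sqrt(0.05 * 0.95 / pr$n_units)
  expect_true(all(abs(pr$firing_prob - 1 / 20) < 4 * se))
})

test_that("phase profile errors without gated units", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 30, seed = 35))
  ph <- gamma_phase(g$rec)
  units <- structure(
    list(times = numeric(0), amplitudes = numeric(0), gated = logical(0),
         waveforms = matrix(0, 0, 0), fs = 5000, snippet_ms = 2),
    class = "unit_events")
  expect_error(phase_profile(units, ph), "no units")
})

test_that("average gamma cycle reproduces a sinusoid and is linear", {
  rec <- sine_recording(f = 40, amp_mV = 0.1, dur = 30)
  ph <- gamma_phase(rec)
  avg <- average_gamma_cycle(ph)
  expect_gte(avg$n_cycles, 10)
  expect_equal(max(avg$amplitude_mV), 0.1, tolerance = 0.01)
  expect_equal(which.min(avg$amplitude_mV), 1, tolerance = 5)
  rec2 <- recording(rec$samples * 2, rec$fs)
  avg2 <- average_gamma_cycle(gamma_phase(rec2))
  expect_equal(avg2$amplitude_mV, avg$amplitude_mV * 2, tolerance = 0.01)
  expect_error(average_gamma_cycle(gamma_phase(sine_recording(dur = 0.2))),
               "cycles")
})

test_that("spike waveform features recover a template and its ratio", {
  fs <- 5000
  hw <- 10  # +/- 2 ms at 5 kHz
  # triangular template: height 0.06 mV, width at half height 0.5 ms
  half_w_samp <- 0.5e-3 * fs           # 2.5 samples
  # value 0.5 at half_w_samp/2 from the apex -> width at half height 0.5 ms
  tri <- pmax(0, 1 - abs(-hw:hw) / half_w_samp) * 0.06
  n <- 40
  units <- structure(
    list(times = seq_len(n) / 10, amplitudes = rep(0.06, n),
         gated = rep(TRUE, n),
         waveforms = matrix(rep(tri, n), n, byrow = TRUE), fs = fs,
         snippet_ms = 2),
    class = "unit_events")
  f <- spike_waveform_features(units)
  expect_equal(f$height_mV, 0.06, tolerance = 0.05)
  expect_equal(f$width_at_half_height_ms, 0.5, tolerance = 0.05)
  expect_equal(f$height_to_width_ratio,
               f$height_mV / f$width_at_half_height_ms, tolerance = 1e-6)
  expect_equal(f$n_spikes_in_window, n)
})
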