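test_that("generators are pure functions of (config, seed)", {
  a <- gen_gamma_lfp(gamma_sim_config(duration_s = 5, seed = 3))
  b <- gen_gamma_lfp(gamma_sim_config(duration_s = 5, seed = 3))
  expect_identical(a$rec$samples, b$rec$samples)
  c <- gen_gamma_lfp(gamma_sim_config(duration_s = 5, seed = 4))
  expect_false(identical(a$rec$samples, c$rec$samples))

  s1 <- gen_swr_train(swr_sim_config(duration_s = 10, seed = 5))
  s2 <- gen_swr_train(swr_sim_config(duration_s = 10, seed = 5))
  expect_identical(s1$rec$samples, s2$rec$samples)

  f1 <- gen_fepsp_sweeps(fepsp_sim_config(seed = 6))
  f2 <- gen_fepsp_sweeps(fepsp_sim_config(seed = 6))
  expect_identical(f1$io_sweeps[[3]]$samples, f2$io_sweeps[[3]]$samples)

  # generators do not disturb the caller's RNG stream
  set.seed(10); before <- rnorm(1)
  set.seed(10); invisible(gen_gamma_lfp(gamma_sim_config(duration_s = 2,
                                                         seed = 99)))
  expect_identical(rnorm(1), before)
})

test_that("gamma generator hits its nominal frequency and power scaling", {
  g <- gen_gamma_lfp(gamma_sim_config(peak_f_hz = 40, seed = 42))
  m <- gamma_scalar_metrics(power_spectrum(g$rec))
  expect_lte(abs(m$peak_f_hz - 40), 5000 / 4096)
  g2 <- gen_gamma_lfp(gamma_sim_config(peak_f_hz = 40, seed = 42,
                                       amplitude_uV = 120))
  m2 <- gamma_scalar_metrics(power_spectrum(g2$rec))
  # amplitude x2 -> oscillatory band power x4 (subtract the shared
  # background contribution before comparing)
  noise <- gen_gamma_lfp(gamma_sim_config(peak_f_hz = 40, seed = 42,
                                          amplitude_uV = 0))
  bg <- gamma_scalar_metrics(power_spectrum(noise$rec))$integrated_power_uV2
  expect_equal((m2$integrated_power_uV2 - bg) /
                 (m$integrated_power_uV2 - bg), 4, tolerance = 0.05)
  # expected band power from the config is realized
  expect_equal(m$integrated_power_uV2 - bg, g$truth$band_power_uV2,
               tolerance = 0.1)
})

test_that("generator log power spans the published range at defaults", {
  g <- gen_gamma_lfp(gamma_sim_config(seed = 2))
  lp <- log_power(gamma_scalar_metrics(power_spectrum(g$rec))$integrated_power_uV2)
  expect_gt(lp, 3.0)
  expect_lt(lp, 4.0)
})

test_that("unit generator produces Poisson counts locked at the target
           phase", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 120, seed = 55))
  u <- gen_locked_units(g, unit_sim_config(rate_hz = 5, kappa = 2,
                                           pref_phase_deg = 270, seed = 56))
  expect_equal(u$truth$n_spikes, 600, tolerance = 3 * sqrt(600) / 600)
  z <- mean(exp(1i * u$truth$phases_deg * pi / 180))
  expect_lte(abs((Arg(z) * 180 / pi) %% 360 - 270), 10)
  # ground-truth phases agree with the generator's own per-sample phase
  idx <- round(u$truth$times_s * g$rec$fs) + 1
  diffs <- abs(g$truth$phase_deg[idx] - u$truth$phases_deg)
  diffs <- pmin(diffs, 360 - diffs)
  expect_lt(stats::median(diffs), 10)
})

test_that("swr generator: empty at zero incidence, enforced separation,
           analytic area", {
  g0 <- gen_swr_train(swr_sim_config(incidence_hz = 0, seed = 1))
  expect_equal(g0$truth$n_events, 0)
  g <- gen_swr_train(swr_sim_config(incidence_hz = 1.2, seed = 2))
  expect_true(all(diff(g$truth$times_s) >= 0.2 - 1e-9))
  expect_equal(g$truth$sw_area_mV_ms, 0.2 * 0.01 * sqrt(2 * pi) * 1000,
               tolerance = 1e-9)
})

test_that("fepsp generator: zero gains give flat sweeps with missing
           metrics and I-O amplitudes are monotone", {
  flat <- gen_fepsp_sweeps(fepsp_sim_config(fv_gain_mV_per_uA = 0,
                                            fepsp_gain_mV_per_uA = 0,
                                            noise_mV = 0.001, seed = 3))
  expect_true(is.na(fepsp_slope(flat$io_sweeps[[5]])$slope_V_per_s))
  expect_true(is.na(fiber_volley_amplitude(flat$io_sweeps[[5]])))
  fe <- gen_fepsp_sweeps(fepsp_sim_config(seed = 4))
  expect_true(all(diff(fe$truth$fepsp_amp_mV) > 0))
})
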