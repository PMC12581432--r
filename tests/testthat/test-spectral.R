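test_that("FFT block of 4096 samples at 5 kHz gives 1.2207 Hz resolution", {
  rec <- sine_recording(dur = 2)
  ps <- power_spectrum(rec, analysis_config(nfft = 4096))
  expect_equal(ps$df, 5000 / 4096)
  expect_equal(round(ps$df, 3), 1.221)
})

test_that("band-summed power of a pure sinusoid is A^2/2 in uV^2", {
  # 0.1 mV = 100 uV amplitude at 40 Hz -> 20-80 Hz power ~ 100^2/2
  rec <- sine_recording(f = 40, amp_mV = 0.1, dur = 120)
  m <- gamma_scalar_metrics(power_spectrum(rec))
  expect_equal(m$integrated_power_uV2, 5000, tolerance = 0.01)
  expect_equal(m$peak_f_hz, 40, tolerance = 5000 / 4096)
})

test_that("Parseval: total spectral power matches time-domain variance", {
  set.seed(11)
  rec <- recording(rnorm(600000, 0, 0.05), fs = 5000)
  ps <- power_spectrum(rec)
  expect_equal(sum(ps$power), stats::var(rec$samples) * 1e6,
               tolerance = 0.01)
})

test_that("power scales quadratically and is monotone in band width", {
  g <- gen_gamma_lfp(gamma_sim_config(duration_s = 30, seed = 4))
  ps1 <- power_spectrum(g$rec)
  rec2 <- recording(g$rec$samples * 2, g$rec$fs)
  ps2 <- power_spectrum(rec2)
  expect_equal(ps2$power, ps1$power * 4, tolerance = 1e-10)
  m_narrow <- gamma_scalar_metrics(ps1, band = c(30, 50))
  m_wide <- gamma_scalar_metrics(ps1, band = c(20, 80))
  expect_gte(m_wide$integrated_power_uV2, m_narrow$integrated_power_uV2)
})

test_that("all-zero signal yields an all-zero spectrum", {
  rec <- recording(numeric(5000), fs = 5000)
  ps <- power_spectrum(rec, analysis_config(nfft = 1024))
  expect_true(all(ps$power == 0))
  expect_error(power_spectrum(recording(1:10, 5000)), "shorter")
})

test_that("scalar metrics handle single-bin and tied peaks", {
  f <- seq(0, 100, by = 0.5)
  mk <- function(p) structure(
    list(freqs = f, power = p, df = 0.5, nfft = 1, n_blocks = 1),
    class = "power_spectrum")
  p1 <- numeric(length(f)); p1[f == 40] <- 7
  m <- gamma_scalar_metrics(mk(p1))
  expect_equal(m$integrated_power_uV2, 7)
  expect_equal(m$peak_power_uV2, 7)
  expect_equal(m$peak_f_hz, 40)
  # tie at 30 and 50 -> lowest frequency wins
  p2 <- numeric(length(f)); p2[f == 30] <- 5; p2[f == 50] <- 5
  expect_equal(gamma_scalar_metrics(mk(p2))$peak_f_hz, 30)
  expect_error(gamma_scalar_metrics(mk(p1), band = c(50, 50)), "empty band")
})

test_that("half band width matches the analytic FWHM of a Gaussian bump", {
  f <- seq(0, 100, by = 0.5)
  sigma <- 3
  ps <- structure(
    list(freqs = f, power = exp(-(f - 35)^2 / (2 * sigma^2)), df = 0.5,
         nfft = 1, n_blocks = 1),
    class = "power_spectrum")
  expect_equal(half_band_width(ps, 35), 2.3548 * sigma, tolerance = 0.01)
})

test_that("half band width is missing, not zero, when undefined", {
  f <- seq(0, 100, by = 0.5)
  flat <- structure(
    list(freqs = f, power = rep(1, length(f)), df = 0.5, nfft = 1,
         n_blocks = 1),
    class = "power_spectrum")
  expect_true(is.na(half_band_width(flat, 40)))
  # single-bin peak with zero neighbours: HBW at most two bins
  p <- numeric(length(f)); p[f == 40] <- 1
  onebin <- structure(
    list(freqs = f, power = p, df = 0.5, nfft = 1, n_blocks = 1),
    class = "power_spectrum")
  expect_lte(half_band_width(onebin, 40), 2 * 0.5)
})

test_that("gamma bump generated at 35 Hz is recovered within one bin", {
  g <- gen_gamma_lfp(gamma_sim_config(peak_f_hz = 35, seed = 9,
                                      duration_s = 60))
  m <- gamma_scalar_metrics(power_spectrum(g$rec))
  expect_lte(abs(m$peak_f_hz - 35), 5000 / 4096)
})

test_that("inclusion rule uses strict inequalities on both thresholds", {
  cfg <- analysis_config()
  m <- function(pp, pf) list(peak_power_uV2 = pp, peak_f_hz = pf)
  expect_false(passes_gamma_inclusion(m(10.0, 35), cfg))  # boundary power
  expect_false(passes_gamma_inclusion(m(50, 20.0), cfg))  # boundary freq
  expect_true(passes_gamma_inclusion(m(11, 35), cfg))
  expect_false(passes_gamma_inclusion(m(50, 19), cfg))
  expect_false(passes_gamma_inclusion(m(9, 35), cfg))
})
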