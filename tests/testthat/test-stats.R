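# Published group summaries used as worked examples (mean, SEM, n):
# log gamma power and log peak power under carbachol, log power under
# DHPG, and the autocorrelation decay constant tau under kainate.
tab_cch_logpow <- list(wt = group_summary(3.329, 0.09448, 24),
                       ko = group_summary(3.825, 0.07796, 35))
tab_cch_logpk  <- list(wt = group_summary(2.400, 0.11640, 24),
                       ko = group_summary(2.903, 0.09264, 35))
tab_dhpg_logpow <- list(wt = group_summary(3.082, 0.09997, 22),
                        ko = group_summary(3.383, 0.09476, 26))
tab_ka_tau <- list(wt = group_summary(19.71, 1.506, 29),
                   ko = group_summary(13.78, 1.065, 23))

test_that("pooled t from summaries reproduces published statistics", {
  r1 <- pooled_t_from_summary(tab_cch_logpow$wt, tab_cch_logpow$ko)
  expect_equal(r1$df, 57)
  expect_equal(abs(r1$statistic), 4.055, tolerance = 0.005)
  expect_lt(r1$p, 0.001)

  r2 <- pooled_t_from_summary(tab_cch_logpk$wt, tab_cch_logpk$ko)
  expect_equal(abs(r2$statistic), 3.410, tolerance = 0.005)

  r3 <- pooled_t_from_summary(tab_dhpg_logpow$wt, tab_dhpg_logpow$ko)
  expect_equal(r3$df, 46)
  expect_equal(abs(r3$statistic), 2.179, tolerance = 0.005)

  r4 <- pooled_t_from_summary(tab_ka_tau$wt, tab_ka_tau$ko)
  expect_equal(r4$df, 50)
  expect_equal(abs(r4$statistic), 3.056, tolerance = 0.005)
})

test_that("identical summaries give t = 0, p = 1", {
  a <- group_summary(1.5, 0.2, 10)
  r <- pooled_t_from_summary(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("summary path equals the raw-data pooled t", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(sample(5:40, 1), 0.5)
    rs <- pooled_t_from_summary(group_summary_from_raw(x),
                                group_summary_from_raw(y))
    rt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(rs$statistic, unname(rt$statistic), tolerance = 1e-10)
    expect_equal(rs$p, rt$p.value, tolerance = 1e-10)
  }
})

test_that("Cohen's d and its interval reproduce published effect sizes", {
  d1 <- cohens_d_ci(tab_cch_logpow$wt, tab_cch_logpow$ko)
  expect_equal(d1$d, -1.07, tolerance = 0.01)
  expect_equal(d1$lo, -1.63, tolerance = 0.01)
  expect_equal(d1$hi, -0.52, tolerance = 0.01)

  d2 <- cohens_d_ci(tab_ka_tau$wt, tab_ka_tau$ko)
  expect_equal(d2$d, 0.85, tolerance = 0.01)
  expect_equal(d2$lo, 0.28, tolerance = 0.02)
  expect_equal(d2$hi, 1.42, tolerance = 0.02)
})

test_that("d is zero for equal means and antisymmetric under group swap", {
  a <- group_summary(2, 0.1, 12)
  b <- group_summary(2, 0.15, 15)
  d0 <- cohens_d_ci(a, b)
  expect_equal(d0$d, 0)
  expect_equal(d0$lo, -d0$hi)
  c1 <- group_summary(2.4, 0.1, 12)
  dab <- cohens_d_ci(c1, b)
  dba <- cohens_d_ci(b, c1)
  expect_equal(dab$d, -dba$d)
  expect_equal(dab$lo, -dba$hi)
  expect_equal(dab$hi, -dba$lo)
})

test_that("normality routing follows Shapiro-Wilk screening", {
  set.seed(7)
  g1 <- rnorm(30); g2 <- rnorm(30, 0.3)
  expect_equal(route_test(g1, g2), "student_t")
  skew <- exp(rnorm(30, 0, 1.5))
  expect_equal(route_test(g1, skew), "mann_whitney")
  expect_error(route_test(c(1, 2), g2), "at least 3")
  r <- compare_groups(g1, skew)
  expect_equal(r$test_name, "mann_whitney")
  expect_true(is.na(r$df))
})

test_that("pooled t holds its nominal 5% size under the null", {
  set.seed(2024)
  reps <- 2000
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(15); y <- rnorm(15)
    r <- pooled_t_from_summary(group_summary_from_raw(x),
                               group_summary_from_raw(y))
    if (r$p < 0.05) rej <- rej + 1L
  }
  expect_equal(rej / reps, 0.05, tolerance = 0.01 / 0.05)
})

test_that("binwise Welch comparison controls type I error on null data and
           localizes a real phase shift", {
  set.seed(99)
  mk_prof <- function(shift = 0, n = 12) {
    lapply(seq_len(n), function(i) {
      ph <- (rnorm(400, 180 + shift, 60)) %% 360
      counts <- tabulate(pmin(findInterval(ph, seq(0, 360, by = 18)), 20),
                         nbins = 20)
      p <- counts / sum(counts)
      structure(list(bin_centers_deg = seq(9, 351, by = 18),
                     firing_prob = p, activation = cumsum(p),
                     n_units = 400),
                class = "phase_profile")
    })
  }
  null_res <- binwise_welch(mk_prof(), mk_prof())
  expect_lte(mean(null_res$significant), 0.15)
  shift_res <- binwise_welch(mk_prof(0), mk_prof(90))
  expect_gt(mean(shift_res$significant), 0.3)
  expect_true(nrow(shift_res$ranges_deg) >= 1)
  expect_error(binwise_welch(mk_prof()[1], mk_prof()), "at least 2")
})

test_that("log power is base 10 and rejects non-positive input", {
  expect_equal(log_power(1000), 3)
  expect_equal(log_power(10^3.329), 3.329)
  expect_error(log_power(0), "positive")
  expect_error(log_power(-5), "positive")
})
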