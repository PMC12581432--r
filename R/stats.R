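#' Group summary (mean, SEM, n)
#'
#' Printed group summaries (as in results tables reporting mean +/- SEM
#' with the group size from the figure legend) are sufficient to
#' reconstruct the pooled two-sample t statistic and Cohen's d, since
#' `SD = SEM * sqrt(n)`.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (> 0).
#' @param n Group size (>= 2).
#' @return A list of class `"group_summary"`.
#' @export
group_summary <- function(mean, sem, n) {
  if (n < 2) stop("n must be at least 2")
  if (!is.finite(sem) || sem <= 0) stop("sem must be positive")
  structure(list(mean = mean, sem = sem, n = as.integer(n)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param x Numeric vector of raw observations.
#' @export
group_summary_from_raw <- function(x) {
  group_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}

#' Pooled two-sample t test from printed summaries
#'
#' Student's two-tailed t with pooled variance and `df = n1 + n2 - 2`,
#' reconstructed from (mean, SEM, n) per group. Identical to the raw-data
#' pooled t whenever the raw samples realize the summaries.
#'
#' @param a,b [group_summary()] objects.
#' @return A list of class `"test_result"`: `statistic`, `df`, `p`,
#'   `test_name = "student_t"`, plus effect size fields `d`, `d_ci`
#'   from [cohens_d_ci()].
#' @export
pooled_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  s1 <- a$sem * sqrt(a$n)
  s2 <- b$sem * sqrt(b$n)
  df <- a$n + b$n - 2L
  sp <- sqrt(((a$n - 1) * s1^2 + (b$n - 1) * s2^2) / df)
  se <- sp * sqrt(1 / a$n + 1 / b$n)
  t <- (a$mean - b$mean) / se
  d <- cohens_d_ci(a, b)
  structure(
    list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df),
         d = d$d, d_ci = c(d$lo, d$hi), test_name = "student_t"),
    class = "test_result"
  )
}

#' Cohen's d with 95% confidence interval from summaries
#'
#' `d = (mean_a - mean_b) / pooled SD`, with the normal-approximation
#' standard error `sqrt((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2)))` and a
#' z-based interval (this convention reproduces published intervals such
#' as d = -1.07, CI [-1.63, -0.52] to two decimals).
#'
#' @param a,b [group_summary()] objects.
#' @param level Confidence level (default 0.95).
#' @return A list: `d`, `lo`, `hi`.
#' @export
cohens_d_ci <- function(a, b, level = 0.95) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  s1 <- a$sem * sqrt(a$n)
  s2 <- b$sem * sqrt(b$n)
  sp <- sqrt(((a$n - 1) * s1^2 + (b$n - 1) * s2^2) / (a$n + b$n - 2))
  if (sp == 0) stop("pooled SD is zero")
  d <- (a$mean - b$mean) / sp
  n1 <- a$n; n2 <- b$n
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(d = d, lo = d - z * se, hi = d + z * se)
}

#' Normality-routed choice of two-group test
#'
#' Both groups are screened with the Shapiro-Wilk test at alpha = 0.05;
#' the parametric Student t is used only when both pass, otherwise the
#' Mann-Whitney U test.
#'
#' @param samples_a,samples_b Raw observations (n >= 3 each).
#' @param alpha Normality screening level.
#' @return `"student_t"` or `"mann_whitney"`.
#' @export
route_test <- function(samples_a, samples_b, alpha = 0.05) {
  if (length(samples_a) < 3L || length(samples_b) < 3L)
    stop("need at least 3 observations per group")
  pa <- stats::shapiro.test(samples_a)$p.value
  pb <- stats::shapiro.test(samples_b)$p.value
  if (pa > alpha && pb > alpha) "student_t" else "mann_whitney"
}

#' Run the routed two-group comparison on raw data
#'
#' @inheritParams route_test
#' @return A list of class `"test_result"`: `statistic`, `df` (NA for
#'   Mann-Whitney), `p`, `d`, `d_ci`, `test_name`.
#' @export
compare_groups <- function(samples_a, samples_b, alpha = 0.05) {
  choice <- route_test(samples_a, samples_b, alpha)
  d <- cohens_d_ci(group_summary_from_raw(samples_a),
                   group_summary_from_raw(samples_b))
  if (choice == "student_t") {
    ht <- stats::t.test(samples_a, samples_b, var.equal = TRUE)
    structure(list(statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p = ht$p.value,
                   d = d$d, d_ci = c(d$lo, d$hi), test_name = "student_t"),
              class = "test_result")
  } else {
    ht <- stats::wilcox.test(samples_a, samples_b, exact = FALSE)
    structure(list(statistic = unname(ht$statistic), df = NA_real_,
                   p = ht$p.value, d = d$d, d_ci = c(d$lo, d$hi),
                   test_name = "mann_whitney"),
              class = "test_result")
  }
}

#' Per-phase-bin Welch comparison of firing-probability profiles
#'
#' For each phase bin, the firing probabilities across the slices of the
#' two groups are compared with Welch's t-test (no equal-SD assumption);
#' contiguous runs of bins with `p < alpha` are reported as significant
#' ranges. No multiplicity correction is applied by default; Holm
#' adjustment is available.
#'
#' @param profiles_a,profiles_b Lists of `phase_profile` objects
#'   ([phase_profile()]), >= 2 per group, identical binning.
#' @param what Compare `"firing_prob"` (default) or `"activation"`.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A list: `bin_centers_deg`, `p`, `significant` (logical),
#'   `ranges_deg` (data frame `from_deg`, `to_deg`).
#' @export
binwise_welch <- function(profiles_a, profiles_b, what = "firing_prob",
                          alpha = 0.05, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (length(profiles_a) < 2L || length(profiles_b) < 2L)
    stop("need at least 2 profiles per group")
  centers <- profiles_a[[1L]]$bin_centers_deg
  chk <- function(p) identical(p$bin_centers_deg, centers)
  if (!all(vapply(profiles_a, chk, logical(1))) ||
      !all(vapply(profiles_b, chk, logical(1))))
    stop("profiles must share the same phase binning")
  ma <- t(vapply(profiles_a, function(p) p[[what]], numeric(length(centers))))
  mb <- t(vapply(profiles_b, function(p) p[[what]], numeric(length(centers))))
  p <- vapply(seq_along(centers), function(j) {
    stats::t.test(ma[, j], mb[, j], var.equal = FALSE)$p.value
  }, numeric(1))
  if (adjust == "holm") p <- stats::p.adjust(p, "holm")
  sig <- p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  halfbin <- (centers[2L] - centers[1L]) / 2
  ranges <- data.frame(
    from_deg = centers[starts[r$values]] - halfbin,
    to_deg = centers[ends[r$values]] + halfbin
  )
  list(bin_centers_deg = centers, p = p, significant = sig,
       ranges_deg = ranges)
}

#' Base-10 log transform of gamma power
#'
#' Gamma power in vitro varies over orders of magnitude, so group
#' comparisons of integrated or peak power are performed on log10 values
#' (powers of order 10^3 uV^2 give log powers around 3, matching the
#' published scale).
#'
#' @param x Power in uV^2 (> 0).
#' @return `log10(x)`.
#' @export
log_power <- function(x) {
  if (any(!is.finite(x) | x <= 0)) stop("power must be positive")
  log10(x)
}
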