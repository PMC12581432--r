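# Shared fixtures: small deterministic signals built in code.

fs_default <- 5000

sine_recording <- function(f = 40, amp_mV = 0.1, dur = 10, fs = fs_default,
                           phase = 0) {
  t <- (0:(dur * fs - 1)) / fs
  recording(amp_mV * sin(2 * pi * f * t + phase), fs)
}

# circular mean (deg) of a phase profile
profile_circ_mean <- function(profile) {
  z <- sum(profile$firing_prob * exp(1i * profile$bin_centers_deg * pi / 180))
  (Arg(z) * 180 / pi) %% 360
}

profile_resultant <- function(profile) {
  Mod(sum(profile$firing_prob * exp(1i * profile$bin_centers_deg * pi / 180)))
}

# match detected event times against ground truth within a tolerance (s);
# returns counts for recall/precision
match_events <- function(detected, truth, tol) {
  tp <- sum(vapply(truth, function(tt) any(abs(detected - tt) < tol),
                   logical(1)))
  fp <- sum(vapply(detected, function(d) !any(abs(truth - d) < tol),
                   logical(1)))
  list(tp = tp, fp = fp, n_truth = length(truth), n_det = length(detected))
}
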