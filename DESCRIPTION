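Package: gammasync
Title: Gamma-Oscillation, Sharp Wave-Ripple and Evoked Field-Potential
    Analysis for In Vitro Hippocampal LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for pharmacologically induced gamma
    oscillations and spontaneous sharp wave-ripples recorded
    extracellularly in hippocampal slices. Implements block-averaged
    power spectra with gamma scalar metrics (integrated 20-80 Hz power,
    peak power and frequency, half band width) and a slice-inclusion
    rule; autocorrelogram synchrony metrics (2nd positive peak,
    exponential decay constant tau); multi-unit spike extraction with
    wavelet denoising and gamma-phase coupling profiles; a sharp
    wave-ripple detector with triple-point-minimax ripple amplitudes;
    evoked fEPSP slope, fiber-volley, transmission-rate and paired-pulse
    metrics; the group-comparison statistics used for genotype contrasts
    (pooled t from summaries, Cohen's d with confidence interval,
    normality-routed test choice, per-phase-bin Welch tests); and seeded
    synthetic-LFP generators with exported ground truth for every
    recovery test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
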