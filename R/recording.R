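#' Construct a single-channel extracellular recording
#'
#' The basic container for all analyses: a uniformly sampled voltage trace
#' in millivolts with its sampling rate. Recordings are plain lists of class
#' `"recording"` so they serialize trivially and index cheaply.
#'
#' @param samples Numeric vector of voltage samples in mV. Must be non-empty
#'   and finite.
#' @param fs Sampling rate in Hz (> 0). In vitro LFP data analysed here are
#'   sampled at 5 kHz.
#' @param t0 Start time of the first sample in seconds.
#' @param label Free-text channel/condition tag.
#' @return An object of class `"recording"` with elements `samples`, `fs`,
#'   `t0`, `label`.
#' @examples
#' rec <- recording(sin(2 * pi * 40 * seq(0, 1, by = 1 / 5000)), fs = 5000)
#' duration(rec)
#' @export
recording <- function(samples, fs, t0 = 0, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("samples must be non-empty")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number (Hz)")
  structure(
    list(samples = samples, fs = fs, t0 = t0, label = as.character(label)[1L]),
    class = "recording"
  )
}

#' @rdname recording
#' @param x A `recording`.
#' @export
is_recording <- function(x) inherits(x, "recording")

#' Duration of a recording in seconds
#' @param rec A `recording`.
#' @return Length of the trace in seconds (`length(samples) / fs`).
#' @export
duration <- function(rec) {
  stopifnot(is_recording(rec))
  length(rec$samples) / rec$fs
}

#' Sample times of a recording
#' @param rec A `recording`.
#' @return Numeric vector of absolute sample times in seconds.
#' @export
sample_times <- function(rec) {
  stopifnot(is_recording(rec))
  rec$t0 + (seq_along(rec$samples) - 1L) / rec$fs
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d samples @ %g Hz (%.3f s)%s\n",
    length(x$samples), x$fs, duration(x),
    if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

#' Extract a contiguous segment of a recording
#'
#' Analyses operate on artifact-free windows (conventionally 120 s) cut out
#' of longer recordings; no resampling is performed and window choice is the
#' caller's responsibility.
#'
#' @param rec A `recording`.
#' @param t_start Absolute start time in seconds (>= `rec$t0`).
#' @param duration_s Window length in seconds.
#' @return A `recording` holding the sub-trace, with `t0 = t_start`.
#' @export
extract_segment <- function(rec, t_start, duration_s) {
  stopifnot(is_recording(rec))
  if (t_start < rec$t0 - 1e-12)
    stop("t_start precedes the start of the recording")
  i0 <- as.integer(round((t_start - rec$t0) * rec$fs)) + 1L
  n <- as.integer(round(duration_s * rec$fs))
  if (n < 1L) stop("duration_s must cover at least one sample")
  if (i0 + n - 1L > length(rec$samples))
    stop("requested window extends beyond the end of the recording")
  recording(rec$samples[i0:(i0 + n - 1L)], rec$fs,
            t0 = rec$t0 + (i0 - 1L) / rec$fs, label = rec$label)
}

#' Analysis configuration
#'
#' Bundles every numeric constant of the pipeline, with defaults matching
#' the standard analysis of 5 kHz in vitro recordings: a 4096-sample FFT
#' block (1.2207 Hz resolution), the 20-80 Hz gamma band and its inclusion
#' thresholds (peak power > 10 uV^2, peak frequency > 20 Hz), the 15-45 Hz
#' band used for gamma-phase extraction, the 500-3000 Hz unit band with a
#' 0.0125 mV amplitude floor and upper-quartile gating, and the sharp
#' wave-ripple constants (45 Hz low-pass, 3 SD thresholds, 100 ms minimum
#' separation, 125 ms ripple window, 120-300 Hz ripple band, 75% asymmetry
#' cap).
#'
#' @param nfft Samples per FFT block.
#' @param window_name Taper; only `"hann"` is implemented.
#' @param overlap_frac Block overlap fraction in `[0, 1)`.
#' @param gamma_band Gamma analysis band (Hz).
#' @param mua_gamma_band Band used for the phase representation of gamma
#'   cycles (Hz).
#' @param unit_band Multi-unit extraction band (Hz); the top edge is clipped
#'   to 0.9 x Nyquist when the sampling rate cannot support it.
#' @param ripple_band Ripple band (Hz).
#' @param sw_lowpass_hz Sharp-wave low-pass corner (Hz).
#' @param inclusion_peak_power_uV2,inclusion_peak_f_hz Slice-inclusion
#'   thresholds (strict inequalities).
#' @param unit_amp_floor_mV Minimum unit amplitude (mV).
#' @param sw_sd_mult,ripple_sd_mult Detection thresholds in SDs.
#' @param sw_min_sep_ms Minimum separation between sharp waves (ms).
#' @param ripple_win_ms Ripple analysis window centred on the SW maximum (ms).
#' @param ripple_asym_max Maximum rise/fall asymmetry for ripple inclusion.
#' @param edge_taper_hz Raised-cosine transition width of the FFT filters (Hz).
#' @param seed Integer seed recorded alongside results.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(nfft = 4096L,
                            window_name = "hann",
                            overlap_frac = 0.5,
                            gamma_band = c(20, 80),
                            mua_gamma_band = c(15, 45),
                            unit_band = c(500, 3000),
                            ripple_band = c(120, 300),
                            sw_lowpass_hz = 45,
                            inclusion_peak_power_uV2 = 10,
                            inclusion_peak_f_hz = 20,
                            unit_amp_floor_mV = 0.0125,
                            sw_sd_mult = 3,
                            ripple_sd_mult = 3,
                            sw_min_sep_ms = 100,
                            ripple_win_ms = 125,
                            ripple_asym_max = 0.75,
                            edge_taper_hz = 1,
                            seed = 1L) {
  chk_band <- function(b, nm) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop(sprintf("%s must be positive with lo < hi", nm))
  }
  chk_band(gamma_band, "gamma_band")
  chk_band(mua_gamma_band, "mua_gamma_band")
  chk_band(unit_band, "unit_band")
  chk_band(ripple_band, "ripple_band")
  stopifnot(
    nfft >= 2, overlap_frac >= 0, overlap_frac < 1,
    sw_lowpass_hz > 0, inclusion_peak_power_uV2 > 0,
    inclusion_peak_f_hz > 0, unit_amp_floor_mV > 0,
    sw_sd_mult > 0, ripple_sd_mult > 0, sw_min_sep_ms > 0,
    ripple_win_ms > 0, ripple_asym_max > 0
  )
  structure(as.list(environment())[setdiff(names(formals()), "")],
            class = "analysis_config")
}

#' Read a voltage time series from disk
#'
#' Two plain formats are supported. `"csv"`: either two columns
#' `time_s, voltage_mV`, or a single `voltage_mV` column preceded by a
#' comment header line `# fs=<Hz>`. `"raw_f32"`: little-endian float32
#' samples with a JSON sidecar `<path>.json` holding `fs_hz`, `units`
#' (must be `"mV"`) and optionally `t0_s`. Units are never silently
#' rescaled: anything other than mV is rejected.
#'
#' @param path File to read.
#' @param format `"csv"` or `"raw_f32"`.
#' @return A [recording()].
#' @export
load_timeseries <- function(path, format = c("csv", "raw_f32")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    if (grepl("^#", first)) {
      m <- regmatches(first, regexec("fs\\s*=\\s*([0-9.eE+-]+)", first))[[1]]
      if (length(m) < 2L) stop("sampling rate missing from CSV header")
      fs <- as.numeric(m[2])
      dat <- utils::read.csv(path, comment.char = "#")
      if (ncol(dat) < 1L) stop("no voltage column in CSV")
      v <- dat[[ncol(dat)]]
      t0 <- 0
    } else {
      dat <- utils::read.csv(path, colClasses = "character")
      if (ncol(dat) < 2L)
        stop("sampling rate missing: need a time column or '# fs=' header")
      tt <- suppressWarnings(as.numeric(dat[[1L]]))
      v <- suppressWarnings(as.numeric(dat[[2L]]))
      if (any(is.na(tt)) || any(is.na(v))) {
        bad <- which(is.na(tt) | is.na(v))[1L]
        stop(sprintf("non-numeric value at data row %d", bad))
      }
      dt <- diff(tt)
      if (length(dt) < 1L || any(dt <= 0)) stop("time column must increase")
      fs <- 1 / stats::median(dt)
      t0 <- tt[1L]
    }
    v <- suppressWarnings(as.numeric(v))
    if (any(is.na(v))) {
      stop(sprintf("non-numeric value at data row %d", which(is.na(v))[1L]))
    }
    recording(v, fs = fs, t0 = t0)
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stop("sampling rate missing: no sidecar ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs_hz)) stop("sampling rate missing from sidecar")
    units <- if (is.null(meta$units)) "mV" else meta$units
    if (!identical(units, "mV"))
      stop("unknown units '", units, "': only mV is accepted, not rescaled")
    n <- file.size(path) / 4L
    v <- readBin(path, what = "numeric", size = 4L, n = n, endian = "little")
    recording(v, fs = meta$fs_hz,
              t0 = if (is.null(meta$t0_s)) 0 else meta$t0_s)
  }
}

#' Write a recording to disk
#'
#' Counterpart of [load_timeseries()]; round trips are exact for CSV
#' (full-precision decimal) and float32-exact for raw binary.
#'
#' @param rec A [recording()].
#' @param path Output file.
#' @param format `"csv"` (two columns `time_s, voltage_mV`) or `"raw_f32"`
#'   (float32 + JSON sidecar).
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(rec, path, format = c("csv", "raw_f32")) {
  stopifnot(is_recording(rec))
  format <- match.arg(format)
  if (format == "csv") {
    dat <- data.frame(time_s = sample_times(rec), voltage_mV = rec$samples)
    utils::write.csv(format(dat, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    writeBin(as.numeric(rec$samples), path, size = 4L, endian = "little")
    jsonlite::write_json(
      list(fs_hz = rec$fs, units = "mV", t0_s = rec$t0),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
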