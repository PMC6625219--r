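# Preprocessing chain: raw intensity -> optical density -> zero-phase
# band-pass -> modified Beer-Lambert inversion, with a two-step channel
# quality control. Filtering is applied to optical density (before the
# chromophore inversion); both operations are linear, so the order is a
# convention fixed here for determinism.

#' Band-pass filter specification
#'
#' @param low_hz Low cutoff, Hz (default 0.01; removes drift and DC).
#' @param high_hz High cutoff, Hz (default 0.3; removes cardiac and most
#'   respiratory oscillations while passing the hemodynamic response band).
#' @param order Butterworth order (default 3; applied forward-backward, so
#'   the effective magnitude response is squared).
#' @param zero_phase Apply forward-backward (default `TRUE`).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 0.01, high_hz = 0.3, order = 3L,
                        zero_phase = TRUE) {
  assert_that(low_hz > 0 && high_hz > low_hz,
              "need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = zero_phase),
            class = "filter_spec")
}

#' Raw intensity to optical-density change
#'
#' Computes `OD(t) = -ln(I(t) / I0)` per channel and wavelength, where `I0`
#' is the mean intensity over a baseline window (default: the first 10
#' seconds). The OD of the baseline mean itself is zero by construction.
#'
#' @param rec A [recording()].
#' @param baseline_window Length-2 integer sample range for `I0`
#'   (default `c(1, 10 s * fs)` clipped to the recording).
#' @return Numeric array `time x channels x 2` of OD changes, with the
#'   baseline window stored in attribute `baseline_window`.
#' @export
intensity_to_od <- function(rec, baseline_window = NULL) {
  validate_recording(rec)
  d <- dim(rec$intensity)
  if (is.null(baseline_window)) {
    baseline_window <- c(1L, min(d[1], round(10 * rec$sampling_rate)))
  }
  bw <- baseline_window[1]:baseline_window[2]
  i0 <- apply(rec$intensity[bw, , , drop = FALSE], c(2, 3), mean)
  od <- -log(sweep(rec$intensity, c(2, 3), i0, "/"))
  attr(od, "baseline_window") <- baseline_window
  od
}

# Design the Butterworth band-pass for a given sampling rate.
design_bandpass <- function(spec, fs) {
  nyq <- fs / 2
  assert_that(spec$high_hz < nyq,
              "high cutoff must be below the Nyquist frequency")
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                 type = "pass")
}

#' Magnitude response of the default band-pass design
#'
#' Evaluates `|H(f)|` of the designed filter directly from its transfer-
#' function coefficients (squared when `zero_phase`, matching the
#' forward-backward application).
#'
#' @param freqs_hz Frequencies to evaluate, Hz.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, Hz.
#' @return Numeric vector of magnitude gains (linear, not dB).
#' @export
bandpass_response <- function(freqs_hz, spec = filter_spec(), fs = 20) {
  bf <- design_bandpass(spec, fs)
  h1 <- vapply(freqs_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf$b * z^(seq_along(bf$b) - 1)) /
          sum(bf$a * z^(seq_along(bf$a) - 1)))
  }, 0)
  if (spec$zero_phase) h1^2 else h1
}

# Zero-phase filtering of one column with reflective padding to tame the
# long transients of the 0.01 Hz high-pass edge.
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a series
#'
#' Applies the configured Butterworth band-pass along the time axis of a
#' vector, matrix (time x series) or 3-d array (time x channel x layer),
#' forward-backward when `zero_phase` so the result has no phase lag.
#' Edge transients are reduced by odd-symmetric reflection padding.
#'
#' @param x Numeric vector, matrix, or 3-d array with time as first axis.
#' @param spec A [filter_spec()].
#' @param fs Sampling rate, Hz.
#' @return Filtered object of the same shape.
#' @export
bandpass <- function(x, spec = filter_spec(), fs = 20) {
  bf <- design_bandpass(spec, fs)
  n <- if (is.null(dim(x))) length(x) else dim(x)[1]
  assert_that(n > 3 * (2 * spec$order + 1),
              "series too short for the filter order")
  # pad with ~1.5 periods of the low cutoff (capped by series length)
  pad <- as.integer(min(n - 1, round(1.5 * fs / spec$low_hz)))
  apply_ts <- function(col) {
    if (spec$zero_phase) filtfilt_padded(bf, col, pad)
    else as.numeric(signal::filter(bf, col))
  }
  if (is.null(dim(x))) return(apply_ts(x))
  d <- dim(x)
  m <- matrix(x, nrow = d[1])
  out <- vapply(seq_len(ncol(m)), function(j) apply_ts(m[, j]), numeric(d[1]))
  array(out, d, dimnames = dimnames(x))
}

#' Modified Beer-Lambert inversion: optical density to hemoglobin
#'
#' Solves, per channel and time point, the 2x2 linear system relating the
#' optical-density changes at the two wavelengths to `(dHbO, dHbR)` (see
#' [mbll_params()] for the model). Output units are micromolar.
#'
#' @param od Array `time x channels x 2` of OD changes (wavelength axis).
#' @param params An [mbll_params()].
#' @return Array `time x channels x 2` with chromophore axis `[HbO, HbR]`,
#'   uM.
#' @export
mbll <- function(od, params = mbll_params()) {
  d <- dim(od)
  assert_that(length(d) == 3L && d[3] == 2L,
              "od must be a time x channel x 2-wavelength array")
  sys <- mbll_system(params, d[2])
  if (kappa_cond(sys$a) >= 1e12) {
    stop_validation("extinction/DPF system is singular; cannot separate chromophores")
  }
  ainv <- solve(sys$a)
  od_sep <- od / rep(sys$sep, each = d[1])
  hb_m <- matrix(od_sep, ncol = 2L) %*% t(ainv)
  array(hb_m * 1e6, c(d[1], d[2], 2L))  # mol/L -> uM
}

#' Two-step channel quality control
#'
#' Step 1 (signal level): the raw intensity of each channel must stay
#' within a configured dynamic range and its coefficient of variation must
#' lie between `cv_min` (a dead, clipped channel has CV ~ 0) and `cv_max`
#' (unstable coupling). Step 2 (physiology): a channel in good optical
#' contact shows a cardiac oscillation; its intensity periodogram must
#' contain a peak in the 0.5-2 Hz band at least `cardiac_prominence` times
#' the median in-band power. A channel fails overall iff it fails either
#' step.
#'
#' @param rec A [recording()].
#' @param range_min,range_max Allowed mean-intensity range (default
#'   `1e-6` to `1e6` arbitrary units).
#' @param cv_min,cv_max Coefficient-of-variation bounds (defaults `1e-6`
#'   and 0.15).
#' @param cardiac_band Frequency band searched for the cardiac peak
#'   (default `c(0.5, 2)` Hz).
#' @param cardiac_prominence Peak-to-median power ratio required
#'   (default 5).
#' @return A `qc_report`: data frame with per-channel `step1`, `step2`,
#'   `pass`, plus attributes `n_pass`/`n_fail`.
#' @export
quality_control <- function(rec, range_min = 1e-6, range_max = 1e6,
                            cv_min = 1e-6, cv_max = 0.15,
                            cardiac_band = c(0.5, 2),
                            cardiac_prominence = 5) {
  validate_recording(rec)
  d <- dim(rec$intensity)
  assert_that(d[1] >= 30 * rec$sampling_rate,
              "quality control needs at least 30 s of data")
  nch <- d[2]
  step1 <- logical(nch)
  step2 <- logical(nch)
  for (ch in seq_len(nch)) {
    # wavelength-wise checks; a channel passes if both wavelengths do
    ok1 <- ok2 <- logical(2)
    for (k in 1:2) {
      x <- rec$intensity[, ch, k]
      m <- mean(x)
      cv <- stats::sd(x) / m
      ok1[k] <- m >= range_min && m <= range_max &&
        cv >= cv_min && cv <= cv_max
      spec <- stats::spec.pgram(x, plot = FALSE, detrend = TRUE,
                                taper = 0.1)
      f <- spec$freq * rec$sampling_rate
      inband <- f >= cardiac_band[1] & f <= cardiac_band[2]
      pk <- max(spec$spec[inband])
      floor_ <- stats::median(spec$spec[inband])
      ok2[k] <- is.finite(pk / floor_) && pk / floor_ >= cardiac_prominence
    }
    step1[ch] <- all(ok1)
    step2[ch] <- all(ok2)
  }
  report <- data.frame(channel = seq_len(nch), step1 = step1, step2 = step2,
                       pass = step1 & step2)
  structure(report, class = c("qc_report", "data.frame"),
            n_pass = sum(report$pass), n_fail = sum(!report$pass))
}

#' Full preprocessing pipeline
#'
#' Composition, in order: quality control -> optical density -> band-pass
#' (on OD) -> modified Beer-Lambert inversion. Channels failing QC are
#' flagged in the output's quality mask but kept on the channel axis.
#'
#' @param rec A [recording()].
#' @param fspec A [filter_spec()]; `NULL` skips filtering (used by the
#'   forward-inverse oracle).
#' @param params An [mbll_params()].
#' @param qc Run quality control (default `TRUE`; requires >= 30 s of
#'   data).
#' @return An [hb_timeseries()] carrying the recording's events and the QC
#'   mask.
#' @export
preprocess_pipeline <- function(rec, fspec = filter_spec(),
                                params = mbll_params(), qc = TRUE) {
  validate_recording(rec)
  mask <- if (qc) quality_control(rec)$pass else
    rep(TRUE, dim(rec$intensity)[2])
  od <- intensity_to_od(rec, params$baseline_window)
  if (!is.null(fspec)) od <- bandpass(od, fspec, rec$sampling_rate)
  hb <- mbll(od, params)
  hb_timeseries(rec$subject_id, hb, sampling_rate = rec$sampling_rate,
                events = rec$events, quality_mask = mask,
                layout = rec$layout)
}
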