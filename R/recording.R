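#' Construct a raw fNIRS recording
#'
#' A recording bundles the dual-wavelength raw light intensities of one
#' session with the probe geometry and trial events. Intensities are in
#' arbitrary light units and must be strictly positive (they feed a log
#' ratio); the two wavelengths must lie in the 700-1000 nm near-infrared
#' window where oxy- and deoxyhemoglobin dominate absorption.
#'
#' @param subject_id Character scalar.
#' @param intensity Numeric array `time x channels x 2` (wavelength axis
#'   ordered as `wavelengths`), strictly positive.
#' @param sampling_rate Sampling rate in Hz (default 20).
#' @param wavelengths Two wavelengths in nm within `[700, 1000]`
#'   (default `c(690, 830)`; 690 sits at the conventional edge of the
#'   band for continuous-wave instruments).
#' @param events Data frame of trial events with columns `trial`
#'   (0-based index), `onset` (stimulation-onset sample), `click`
#'   (pain-threshold click sample, `NA` if the subject never clicked),
#'   `side` (`"left"`/`"right"`), `threshold_temp` (degrees C).
#' @param layout A `probe_layout`; defaults to [default_layout()].
#' @return A validated `recording` object.
#' @export
recording <- function(subject_id, intensity, sampling_rate = 20,
                      wavelengths = c(690, 830),
                      events = empty_events(), layout = default_layout()) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = as.numeric(sampling_rate),
         wavelengths = as.numeric(wavelengths),
         intensity = intensity,
         events = events,
         layout = layout),
    class = "recording"
  )
  validate_recording(rec)
}

#' Empty trial-event table
#' @return A zero-row events data frame with the canonical columns.
#' @export
empty_events <- function() {
  data.frame(trial = integer(), onset = integer(), click = integer(),
             side = character(), threshold_temp = numeric(),
             stringsAsFactors = FALSE)
}

#' Validate a recording
#'
#' Enforces the recording invariants: two wavelengths in 700-1000 nm,
#' strictly positive intensity, positive sampling rate, event sample
#' indices within the recorded length, threshold click after stimulation
#' onset, threshold temperatures within `[0, 32]` degrees C.
#'
#' @param rec A `recording`.
#' @return The recording, invisibly; errors on violation.
#' @export
validate_recording <- function(rec) {
  assert_that(inherits(rec, "recording"), "not a recording")
  assert_that(length(rec$wavelengths) == 2L,
              "recording must carry exactly 2 wavelengths")
  assert_that(all(rec$wavelengths >= 700 - 10 & rec$wavelengths <= 1000),
              "wavelengths must lie in the near-infrared window (~700-1000 nm)")
  assert_that(is.array(rec$intensity) && length(dim(rec$intensity)) == 3L,
              "intensity must be a time x channel x wavelength array")
  assert_that(dim(rec$intensity)[2] == nrow(rec$layout$channels),
              "intensity channel axis does not match layout")
  assert_that(dim(rec$intensity)[3] == 2L,
              "intensity wavelength axis must have length 2")
  assert_that(all(is.finite(rec$intensity)) && all(rec$intensity > 0),
              "intensity must be strictly positive everywhere")
  assert_that(rec$sampling_rate > 0, "sampling rate must be positive")
  ev <- rec$events
  n <- dim(rec$intensity)[1]
  if (nrow(ev)) {
    assert_that(all(ev$onset >= 1 & ev$onset <= n),
                "event onset outside recorded length")
    clicked <- !is.na(ev$click)
    assert_that(all(ev$click[clicked] >= 1 & ev$click[clicked] <= n),
                "threshold click outside recorded length")
    assert_that(all(ev$click[clicked] > ev$onset[clicked]),
                "threshold click must follow stimulation onset")
    tt <- ev$threshold_temp[!is.na(ev$threshold_temp)]
    assert_that(all(tt >= 0 & tt <= 32),
                "threshold temperature must lie in [0, 32] degrees C")
    assert_that(all(ev$side %in% c("left", "right")),
                "event side must be 'left' or 'right'")
  }
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<recording> subject %s: %d samples x %d channels x 2 wavelengths (%g, %g nm) @ %g Hz, %d trials\n",
    x$subject_id, d[1], d[2], x$wavelengths[1], x$wavelengths[2],
    x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Construct a hemoglobin concentration-change time series
#'
#' The product of the preprocessing chain: per-channel oxygenated (HbO) and
#' deoxygenated (HbR) hemoglobin concentration changes in micromolar, on the
#' canonical channel axis of the probe layout. The chromophore axis order is
#' fixed as `[HbO, HbR]`. Channels failing quality control are flagged in
#' `quality_mask` but never dropped, so the channel axis always matches the
#' layout.
#'
#' @param subject_id Character scalar.
#' @param data Numeric array `time x channels x 2` (`[, , 1]` = HbO,
#'   `[, , 2]` = HbR), units uM.
#' @param sampling_rate Hz.
#' @param events Trial-event table (see [recording()]).
#' @param quality_mask Logical vector, one flag per channel, `TRUE` = keep.
#' @param layout A `probe_layout`.
#' @return A validated `hb_timeseries` object.
#' @export
hb_timeseries <- function(subject_id, data, sampling_rate = 20,
                          events = empty_events(),
                          quality_mask = rep(TRUE, dim(data)[2]),
                          layout = default_layout()) {
  hb <- structure(
    list(subject_id = as.character(subject_id),
         sampling_rate = as.numeric(sampling_rate),
         data = data,
         events = events,
         quality_mask = as.logical(quality_mask),
         layout = layout),
    class = "hb_timeseries"
  )
  validate_hb(hb)
}

#' Validate a hemoglobin time series
#' @param hb An `hb_timeseries`.
#' @return The object, invisibly; errors on violation.
#' @export
validate_hb <- function(hb) {
  assert_that(inherits(hb, "hb_timeseries"), "not an hb_timeseries")
  assert_that(is.array(hb$data) && length(dim(hb$data)) == 3L,
              "data must be a time x channel x chromophore array")
  assert_that(dim(hb$data)[3] == 2L,
              "chromophore axis must have length exactly 2 ([HbO, HbR])")
  assert_that(dim(hb$data)[2] == nrow(hb$layout$channels),
              "channel axis does not match layout")
  assert_that(length(hb$quality_mask) == dim(hb$data)[2],
              "quality mask must cover every channel")
  assert_that(hb$sampling_rate > 0, "sampling rate must be positive")
  invisible(hb)
}

#' @export
print.hb_timeseries <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<hb_timeseries> subject %s: %d samples x %d channels x [HbO, HbR] @ %g Hz (%d/%d channels pass QC)\n",
    x$subject_id, d[1], d[2], x$sampling_rate,
    sum(x$quality_mask), d[2]))
  invisible(x)
}

n_samples <- function(x) {
  if (inherits(x, "recording")) dim(x$intensity)[1] else dim(x$data)[1]
}
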