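# Readers/writers for recordings and derived series. Two formats:
#   "native" - a single JSON container; doubles are serialized as %.17g
#              strings so every float round-trips to the exact same value.
#   "csv"    - a long-format table (time, channel, wavelength, intensity)
#              for toy fixtures, with "#key: value" metadata header lines
#              and a sidecar <path>.events.csv for the trial table.
# SNIRF (HDF5) is recognised but not supported in this build.

SUPPORTED_FORMATS <- c("native", "csv")

layout_to_list <- function(layout) {
  list(emitters = layout$emitters, detectors = layout$detectors,
       channels = layout$channels)
}

layout_from_list <- function(x) {
  lay <- structure(
    list(emitters = as.data.frame(x$emitters),
         detectors = as.data.frame(x$detectors),
         channels = as.data.frame(x$channels)),
    class = "probe_layout"
  )
  validate_layout(lay)
}

events_to_list <- function(ev) {
  list(trial = ev$trial, onset = ev$onset, click = ev$click,
       side = ev$side, threshold_temp = num_to_chr(ev$threshold_temp))
}

events_from_list <- function(x) {
  if (is.null(x) || length(x$trial) == 0L) return(empty_events())
  data.frame(trial = as.integer(x$trial), onset = as.integer(x$onset),
             click = as.integer(x$click), side = as.character(x$side),
             threshold_temp = chr_to_num(x$threshold_temp),
             stringsAsFactors = FALSE)
}

#' Write a recording to disk
#'
#' @param rec A validated `recording`.
#' @param path Output file path.
#' @param format `"native"` (JSON container, lossless) or `"csv"`
#'   (long-format toy fixture; events go to `<path>.events.csv`).
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, format = c("native", "csv")) {
  format <- match.arg(format, c(SUPPORTED_FORMATS, "snirf"))
  if (format == "snirf") {
    stop_config("SNIRF output is not supported in this build; use 'native' or 'csv'")
  }
  validate_recording(rec)
  if (format == "native") {
    obj <- list(
      container = "nirspain-recording", version = 1L,
      subject_id = rec$subject_id,
      sampling_rate = num_to_chr(rec$sampling_rate),
      wavelengths = num_to_chr(rec$wavelengths),
      dim = dim(rec$intensity),
      intensity = num_to_chr(as.vector(rec$intensity)),
      events = events_to_list(rec$events),
      layout = layout_to_list(rec$layout)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                         na = "null", dataframe = "columns")
  } else {
    d <- dim(rec$intensity)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("#container: nirspain-recording-csv"),
      sprintf("#subject_id: %s", rec$subject_id),
      sprintf("#sampling_rate: %s", num_to_chr(rec$sampling_rate)),
      sprintf("#wavelengths: %s,%s", num_to_chr(rec$wavelengths[1]),
              num_to_chr(rec$wavelengths[2])),
      "time,channel,wavelength,intensity"
    ), con)
    grid <- expand.grid(time = seq_len(d[1]), channel = seq_len(d[2]),
                        wavelength = seq_len(d[3]))
    writeLines(sprintf("%d,%d,%s,%s", grid$time, grid$channel,
                       num_to_chr(rec$wavelengths[grid$wavelength]),
                       num_to_chr(as.vector(rec$intensity))), con)
    ev <- rec$events
    utils::write.csv(
      data.frame(trial = ev$trial, onset = ev$onset, click = ev$click,
                 side = ev$side,
                 threshold_temp = num_to_chr(ev$threshold_temp)),
      paste0(path, ".events.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path File written by [write_recording()].
#' @param format `"native"` or `"csv"`.
#' @return A validated `recording`.
#' @export
read_recording <- function(path, format = c("native", "csv")) {
  format <- match.arg(format, c(SUPPORTED_FORMATS, "snirf"))
  if (format == "snirf") {
    stop_config("SNIRF input is not supported in this build; use 'native' or 'csv'")
  }
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  if (format == "native") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$container, "nirspain-recording")) {
      stop_parse("not a nirspain recording container (field 'container')")
    }
    intensity <- array(chr_to_num(obj$intensity), dim = as.integer(obj$dim))
    recording(
      subject_id = obj$subject_id,
      intensity = intensity,
      sampling_rate = chr_to_num(obj$sampling_rate),
      wavelengths = chr_to_num(obj$wavelengths),
      events = events_from_list(obj$events),
      layout = layout_from_list(obj$layout)
    )
  } else {
    header <- readLines(path, n = 10L)
    meta_lines <- grep("^#", header, value = TRUE)
    meta <- strsplit(sub("^#", "", meta_lines), ": ")
    keys <- vapply(meta, `[`, "", 1L)
    vals <- vapply(meta, `[`, "", 2L)
    if (!"sampling_rate" %in% keys) {
      stop_parse("csv recording missing '#sampling_rate' header (field 'sampling_rate')")
    }
    tab <- utils::read.csv(path, comment.char = "#")
    wl <- chr_to_num(strsplit(vals[keys == "wavelengths"], ",")[[1]])
    nt <- max(tab$time)
    nc <- max(tab$channel)
    intensity <- array(NA_real_, c(nt, nc, 2L))
    widx <- match(tab$wavelength, wl)
    intensity[cbind(tab$time, tab$channel, widx)] <- tab$intensity
    if (anyNA(intensity)) {
      stop_parse("csv recording has missing (time, channel, wavelength) cells (field 'intensity')")
    }
    evp <- paste0(path, ".events.csv")
    events <- if (file.exists(evp)) {
      ev <- utils::read.csv(evp, stringsAsFactors = FALSE)
      if (nrow(ev) == 0) empty_events() else
        data.frame(trial = as.integer(ev$trial), onset = as.integer(ev$onset),
                   click = as.integer(ev$click), side = as.character(ev$side),
                   threshold_temp = chr_to_num(ev$threshold_temp),
                   stringsAsFactors = FALSE)
    } else empty_events()
    recording(
      subject_id = vals[keys == "subject_id"],
      intensity = intensity,
      sampling_rate = chr_to_num(vals[keys == "sampling_rate"]),
      wavelengths = wl,
      events = events
    )
  }
}

#' Write a hemoglobin time series to the native JSON container
#'
#' @param hb An `hb_timeseries`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hb <- function(hb, path) {
  validate_hb(hb)
  obj <- list(
    container = "nirspain-hb", version = 1L,
    subject_id = hb$subject_id,
    sampling_rate = num_to_chr(hb$sampling_rate),
    dim = dim(hb$data),
    data = num_to_chr(as.vector(hb$data)),
    quality_mask = hb$quality_mask,
    events = events_to_list(hb$events),
    layout = layout_to_list(hb$layout)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' Read a hemoglobin time series from the native JSON container
#' @param path File written by [write_hb()].
#' @return A validated `hb_timeseries`.
#' @export
read_hb <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "nirspain-hb")) {
    stop_parse("not a nirspain hb container (field 'container')")
  }
  hb_timeseries(
    subject_id = obj$subject_id,
    data = array(chr_to_num(obj$data), dim = as.integer(obj$dim)),
    sampling_rate = chr_to_num(obj$sampling_rate),
    events = events_from_list(obj$events),
    quality_mask = as.logical(obj$quality_mask),
    layout = layout_from_list(obj$layout)
  )
}

#' Write per-sample ground-truth state labels as a sidecar CSV
#'
#' @param truth A `ground_truth` object (see [simulate_subject()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(
    data.frame(sample = seq_along(truth$state), state = truth$state),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth sidecar written by [write_ground_truth()]
#' @param path Sidecar CSV path.
#' @return Integer vector of per-sample state codes.
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.csv(path)
  as.integer(tab$state[order(tab$sample)])
}
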