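#' Canonical 40-channel probe layout
#'
#' Builds the default optode montage used throughout the package: 8 near-
#' infrared emitters and 28 detectors spaced 3 cm apart, yielding 40
#' measurement channels split evenly over four cortical regions -- left and
#' right prefrontal cortex (PFC) and left and right primary somatosensory
#' cortex (S1), 10 channels each. Optode scalp positions carry 10-10 system
#' labels around F3/F4 (PFC) and C3/C4 (S1); the exact coordinates are
#' placeholders, only the region/hemisphere structure is load-bearing.
#'
#' The channel ordering returned here is total and stable: it defines the
#' canonical channel axis of every hemoglobin time series and feature cube
#' produced by the package.
#'
#' @return A `probe_layout` object: a list with `emitters` and `detectors`
#'   data frames (`id`, `position`), and a `channels` data frame with one
#'   row per channel (`channel`, `emitter`, `detector`, `region`,
#'   `hemisphere`, `separation_cm`).
#' @examples
#' layout <- default_layout()
#' table(layout$channels$region)
#' @export
default_layout <- function() {
  regions <- c("PFC-left", "PFC-right", "S1-left", "S1-right")
  hemis <- c("L", "R", "L", "R")
  # 10-10 labels: frontal optodes around F3/F4, central around C3/C4.
  emitter_pos <- c("F3", "AF3", "F4", "AF4", "C3", "C1", "C4", "C2")
  detector_pos <- list(
    c("F1", "F5", "AF7", "FP1", "F7", "FC3", "FC5"),
    c("F2", "F6", "AF8", "FP2", "F8", "FC4", "FC6"),
    c("C5", "CP3", "CP5", "CP1", "FC1", "T7", "P3"),
    c("C6", "CP4", "CP6", "CP2", "FC2", "T8", "P4")
  )
  emitters <- data.frame(
    id = seq_len(8L),
    position = emitter_pos,
    stringsAsFactors = FALSE
  )
  detectors <- data.frame(
    id = seq_len(28L),
    position = unlist(detector_pos),
    stringsAsFactors = FALSE
  )
  # Per region: 2 emitters x 5 of its 7 detectors (overlapping fans) = 10.
  ch <- vector("list", 4L)
  for (r in seq_len(4L)) {
    e1 <- 2L * r - 1L
    e2 <- 2L * r
    d0 <- 7L * (r - 1L)
    ch[[r]] <- data.frame(
      emitter = rep(c(e1, e2), each = 5L),
      detector = c(d0 + 1:5, d0 + 3:7),
      region = regions[r],
      hemisphere = hemis[r],
      stringsAsFactors = FALSE
    )
  }
  channels <- do.call(rbind, ch)
  channels <- cbind(channel = seq_len(nrow(channels)), channels,
                    separation_cm = 3.0)
  layout <- structure(
    list(emitters = emitters, detectors = detectors, channels = channels),
    class = "probe_layout"
  )
  validate_layout(layout)
  layout
}

#' Validate a probe layout
#'
#' Checks the structural invariants of a [default_layout()]-style montage:
#' every channel references an existing emitter and detector, positive
#' source-detector separations, region tags partitioning the channels and
#' hemisphere tags splitting them in half.
#'
#' @param layout A `probe_layout`.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  assert_that(inherits(layout, "probe_layout"), "not a probe_layout")
  ch <- layout$channels
  assert_that(all(ch$emitter %in% layout$emitters$id),
              "channel references unknown emitter")
  assert_that(all(ch$detector %in% layout$detectors$id),
              "channel references unknown detector")
  assert_that(all(ch$separation_cm > 0), "separation must be positive")
  assert_that(all(ch$region %in%
                    c("PFC-left", "PFC-right", "S1-left", "S1-right")),
              "unknown region tag")
  assert_that(all(ch$hemisphere %in% c("L", "R")), "unknown hemisphere tag")
  invisible(layout)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d emitters, %d detectors, %d channels\n",
              nrow(x$emitters), nrow(x$detectors), nrow(x$channels)))
  print(table(x$channels$region))
  invisible(x)
}

#' Channel indices for a cortical region or hemisphere
#'
#' @param layout A `probe_layout`.
#' @param region Optional region tag (`"PFC-left"`, `"PFC-right"`,
#'   `"S1-left"`, `"S1-right"`).
#' @param hemisphere Optional hemisphere (`"L"` or `"R"`).
#' @return Integer channel indices (canonical ordering).
#' @export
region_channels <- function(layout, region = NULL, hemisphere = NULL) {
  ch <- layout$channels
  keep <- rep(TRUE, nrow(ch))
  if (!is.null(region)) keep <- keep & ch$region %in% region
  if (!is.null(hemisphere)) keep <- keep & ch$hemisphere %in% hemisphere
  ch$channel[keep]
}

#' Load a probe layout override from YAML
#'
#' Reads a YAML file with `emitters`, `detectors` and `channels` sections
#' mirroring the fields of [default_layout()]. Fields omitted from the file
#' fall back to the default layout.
#'
#' @param path Path to a YAML file.
#' @return A validated `probe_layout`.
#' @export
layout_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_layout()
  if (!is.null(cfg$emitters)) {
    base$emitters <- do.call(rbind.data.frame, cfg$emitters)
  }
  if (!is.null(cfg$detectors)) {
    base$detectors <- do.call(rbind.data.frame, cfg$detectors)
  }
  if (!is.null(cfg$channels)) {
    ch <- do.call(rbind.data.frame, cfg$channels)
    if (is.null(ch$channel)) ch$channel <- seq_len(nrow(ch))
    if (is.null(ch$separation_cm)) ch$separation_cm <- 3.0
    base$channels <- ch
  }
  validate_layout(base)
}

# State-label convention (also used by the streaming wire format):
#   0 = no pain, 1 = right-side pain, 2 = left-side pain.

#' State-label codes
#'
#' The package-wide label convention for brain states: `0` no pain,
#' `1` right-side pain, `2` left-side pain. The binary detection task pools
#' codes 1 and 2 into a single "pain" class.
#'
#' @return Named integer vector of the three codes.
#' @export
state_codes <- function() {
  c("no-pain" = 0L, "right-pain" = 1L, "left-pain" = 2L)
}

#' Code for a stimulated side
#' @param side `"left"` or `"right"`.
#' @return The 3-class state code for pain on that side.
#' @export
side_to_code <- function(side) {
  assert_that(side %in% c("left", "right"), "side must be 'left' or 'right'")
  if (side == "left") 2L else 1L
}

#' Collapse 3-class labels to the binary pain/no-pain task
#' @param codes Integer vector of state codes in `{0, 1, 2}`.
#' @return Integer vector in `{0, 1}` with 1 = any pain.
#' @export
collapse_binary <- function(codes) {
  assert_that(all(codes %in% 0:2), "state codes must be in {0, 1, 2}")
  as.integer(codes > 0L)
}
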