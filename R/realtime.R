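# Simulated real-time engine: replays a hemoglobin time series sample by
# sample, maintains causal normalization state, assembles the history
# cube at each emitted frame, runs the classifier, and serializes frames
# as newline-delimited JSON that any renderer can consume. Causality is
# structural: no emitted frame uses samples after its own timestamp, so
# truncating the input after time t leaves all frames at <= t unchanged.

#' Streaming engine configuration
#'
#' @param model A trained `nn_model` (or path to a [save_model()]
#'   artifact).
#' @param cube_type 1 or 2 (must match the model's input shape).
#' @param lag Block separation for type-II cubes, samples (default 160).
#' @param normalize Apply causal divide-by-the-mean normalization
#'   (default `FALSE`).
#' @param window_s Normalization window, seconds (default 30).
#' @param emit_every Emit one frame every this many samples (default 1 =
#'   every sample, 20 Hz at the native rate).
#' @return An `engine_config`.
#' @export
engine_config <- function(model, cube_type = 1L, lag = 160L,
                          normalize = FALSE, window_s = 30,
                          emit_every = 1L) {
  if (is.character(model)) model <- load_model(model)
  assert_that(inherits(model, "nn_model"), "model must be an nn_model")
  assert_that(cube_type %in% 1:2, "cube_type must be 1 or 2")
  expected_t <- if (cube_type == 1L) 40L else 80L
  if (model$spec$input_shape[1] != expected_t) {
    stop_config(sprintf(
      "model expects T=%d but cube type %d yields T=%d",
      model$spec$input_shape[1], cube_type, expected_t))
  }
  assert_that(emit_every >= 1L, "emit_every must be >= 1")
  structure(list(model = model, cube_type = as.integer(cube_type),
                 lag = as.integer(lag), normalize = normalize,
                 window_s = window_s, emit_every = as.integer(emit_every)),
            class = "engine_config")
}

#' Run the streaming engine over a recording
#'
#' Emits one frame per `emit_every` samples once enough history has
#' accumulated for a full cube. Each frame carries the current per-channel
#' HbO/HbR values, the predicted state code, class probabilities, and a
#' latency account (`consumed` = samples used, `available` = samples seen).
#' Frame-by-frame output is identical to batch prediction on the same
#' cubes because both share the causal cube assembly and normalization
#' code path.
#'
#' @param hb An [hb_timeseries()].
#' @param engine An [engine_config()].
#' @return List of `stream_frame` lists (possibly empty if the recording
#'   is shorter than one cube), each with fields `t`, `hbo`, `hbr`,
#'   `state`, `prob`, `model`, `consumed`, `available`.
#' @export
run_stream <- function(hb, engine) {
  validate_hb(hb)
  n <- n_samples(hb)
  fs <- hb$sampling_rate
  first <- if (engine$cube_type == 1L) 40L else engine$lag + 40L
  if (n < first) return(list())

  work <- hb
  if (engine$normalize) {
    work <- normalize_hb(hb, window_s = engine$window_s)
  }
  state <- integer(n)  # dummy labels; prediction ignores them
  set <- if (engine$cube_type == 1L) {
    make_type1_cubes(work, state, stride = engine$emit_every)
  } else {
    make_type2_cubes(work, state, lag = engine$lag,
                     stride = engine$emit_every)
  }
  pred <- predict(engine$model, set)
  anchors <- set$anchors$anchor
  model_id <- sprintf("%s/%d-class", engine$model$spec$family,
                      engine$model$spec$n_classes)
  lapply(seq_along(anchors), function(i) {
    a <- anchors[i]
    structure(list(
      t = a / fs,
      hbo = as.numeric(work$data[a, , 1L]),
      hbr = as.numeric(work$data[a, , 2L]),
      state = as.integer(pred$codes[i]),
      prob = as.numeric(pred$prob[i, ]),
      model = model_id,
      consumed = as.integer(a),
      available = as.integer(a)
    ), class = "stream_frame")
  })
}

#' Serialize a frame to one wire-format line
#'
#' Newline-delimited JSON with keys `t`, `hbo` (length 40), `hbr`
#' (length 40), `state`, `prob`, `model`; numbers carry 6 significant
#' digits. Frames containing non-finite payload values are dropped (with
#' a warning) rather than emitted malformed.
#'
#' @param frame A `stream_frame` from [run_stream()].
#' @return A JSON string, or `NULL` if the frame was dropped.
#' @export
serialize_frame <- function(frame) {
  nums <- c(frame$t, frame$hbo, frame$hbr, frame$prob)
  if (any(!is.finite(nums))) {
    warning("dropping stream frame with non-finite payload at t=",
            frame$t)
    return(NULL)
  }
  obj <- list(t = signif(frame$t, 6), hbo = signif(frame$hbo, 6),
              hbr = signif(frame$hbr, 6), state = frame$state,
              prob = signif(frame$prob, 6), model = frame$model)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Parse a wire-format line back into a frame
#' @param line A JSON string from [serialize_frame()].
#' @return A `stream_frame` (without the latency fields).
#' @export
parse_frame <- function(line) {
  obj <- jsonlite::fromJSON(line)
  assert_that(all(c("t", "hbo", "hbr", "state", "prob", "model")
                  %in% names(obj)), "malformed stream frame")
  structure(list(t = obj$t, hbo = obj$hbo, hbr = obj$hbr,
                 state = as.integer(obj$state), prob = obj$prob,
                 model = obj$model),
            class = "stream_frame")
}

#' Reference stream consumer
#'
#' Parses a sequence of wire-format lines, verifies the schema, and
#' tallies the received state codes; stands in for a downstream renderer
#' in integration tests.
#'
#' @param lines Character vector of serialized frames.
#' @return List with `n_frames`, `state_counts` (named tally), and
#'   `t_range`.
#' @export
stream_sink <- function(lines) {
  frames <- lapply(lines, parse_frame)
  states <- vapply(frames, `[[`, 0L, "state")
  ts <- vapply(frames, `[[`, 0, "t")
  assert_that(all(diff(ts) > 0), "timestamps must be strictly increasing")
  assert_that(all(states %in% 0:2), "state codes must be in {0, 1, 2}")
  list(n_frames = length(frames),
       state_counts = table(factor(states, levels = 0:2)),
       t_range = range(ts))
}
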