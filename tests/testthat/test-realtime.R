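# A small trained model shared by the streaming tests (built once).
stream_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_subject(n_trials = 2L, seed = 44)
      hb <- preprocess_pipeline(sim$recording, qc = FALSE)
      set <- make_type1_cubes(hb, sim$truth, stride = 4L)
      spec <- network_spec("ANN", 2, c(40L, 40L, 2L), hidden = 0.25)
      model <- train(build_network(spec, 1), set,
                     train_config(epochs = 2, seed = 2))
      cache <<- list(hb = hb, model = model, truth = sim$truth)
    }
    cache
  }
})

test_that("streaming predictions equal batch predictions bit for bit", {
  fx <- stream_fixture()
  engine <- engine_config(fx$model, cube_type = 1L, normalize = TRUE)
  frames <- run_stream(fx$hb, engine)
  # batch route over the same causal normalization
  nhb <- normalize_hb(fx$hb, window_s = 30)
  set <- make_type1_cubes(nhb, integer(nrow(nhb$data)))
  batch <- predict(fx$model, set)
  expect_equal(length(frames), n_cubes(set))
  got <- vapply(frames, `[[`, 0L, "state")
  expect_identical(got, as.integer(batch$codes))
  probs <- t(vapply(frames, `[[`, numeric(2), "prob"))
  expect_identical(unname(probs), unname(batch$prob))
})

test_that("the engine is causal: truncation never changes past frames", {
  fx <- stream_fixture()
  engine <- engine_config(fx$model, cube_type = 1L, normalize = TRUE,
                          emit_every = 7L)
  full <- run_stream(fx$hb, engine)
  cut <- fx$hb
  keep_n <- 400L
  cut$data <- cut$data[seq_len(keep_n), , , drop = FALSE]
  cut$events <- empty_events()
  truncated <- run_stream(cut, engine)
  prefix <- full[seq_along(truncated)]
  for (f in c("t", "hbo", "hbr", "state")) {
    expect_identical(lapply(truncated, `[[`, f), lapply(prefix, `[[`, f))
  }
  pt <- t(vapply(truncated, `[[`, numeric(2), "prob"))
  pf <- t(vapply(prefix, `[[`, numeric(2), "prob"))
  expect_equal(pt, pf, tolerance = 1e-10)
  expect_true(all(vapply(truncated, `[[`, 0, "t") <= keep_n / 20))
})

test_that("short recordings produce zero frames and a clean exit", {
  fx <- stream_fixture()
  engine <- engine_config(fx$model, cube_type = 1L)
  short <- fx$hb
  short$data <- short$data[1:30, , , drop = FALSE]
  short$events <- empty_events()
  expect_identical(run_stream(short, engine), list())
})

test_that("engine configuration rejects shape mismatches at startup", {
  fx <- stream_fixture()
  expect_error(engine_config(fx$model, cube_type = 2L), "T=")
  expect_error(engine_config(fx$model, cube_type = 1L, emit_every = 0L),
               "emit_every")
})

test_that("wire format round-trips and encodes the state literal", {
  frame <- structure(list(t = 2.05, hbo = seq(-0.5, 0.475, by = 0.025),
                          hbr = rep(0.125, 40), state = 2L,
                          prob = c(0.1, 0.2, 0.7), model = "ANN/3-class",
                          consumed = 41L, available = 41L),
                     class = "stream_frame")
  line <- serialize_frame(frame)
  expect_match(line, "\"state\":2", fixed = TRUE)
  back <- parse_frame(line)
  expect_length(back$hbo, 40L)
  expect_length(back$hbr, 40L)
  expect_equal(back$hbo, frame$hbo, tolerance = 1e-5)
  expect_equal(back$prob, frame$prob, tolerance = 1e-5)
  expect_identical(back$state, 2L)
  # NaN payload is dropped with a warning, never emitted malformed
  bad <- frame
  bad$hbo[3] <- NaN
  expect_warning(out <- serialize_frame(bad), "dropping")
  expect_null(out)
})

test_that("the reference consumer tallies states and checks the schema", {
  fx <- stream_fixture()
  engine <- engine_config(fx$model, cube_type = 1L, emit_every = 25L)
  frames <- run_stream(fx$hb, engine)
  lines <- vapply(frames, serialize_frame, "")
  sink <- stream_sink(lines)
  expect_equal(sink$n_frames, length(frames))
  expect_equal(sum(sink$state_counts), length(frames))
  bad <- sub("\"t\":[0-9.]+", "\"t\":1", lines[2], fixed = FALSE)
  expect_error(stream_sink(c(lines[1], bad, lines[3])),
               "strictly increasing|increasing")
})
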