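test_that("default layout has the canonical montage structure", {
  lay <- default_layout()
  expect_equal(nrow(lay$emitters), 8L)
  expect_equal(nrow(lay$detectors), 28L)
  expect_equal(nrow(lay$channels), 40L)
  expect_true(all(lay$channels$separation_cm == 3.0))
  expect_equal(unname(table(lay$channels$region)),
               rep(10L, 4L), ignore_attr = TRUE)
  expect_equal(unname(table(lay$channels$hemisphere)),
               c(20L, 20L), ignore_attr = TRUE)
  # every channel references a real optode
  expect_true(all(lay$channels$emitter %in% lay$emitters$id))
  expect_true(all(lay$channels$detector %in% lay$detectors$id))
  # deterministic ordering
  expect_identical(lay$channels$channel, seq_len(40L))
  expect_identical(default_layout()$channels, lay$channels)
})

test_that("region and hemisphere selection partition the channels", {
  lay <- default_layout()
  regions <- c("PFC-left", "PFC-right", "S1-left", "S1-right")
  picked <- lapply(regions, function(r) region_channels(lay, r))
  expect_equal(sort(unlist(picked)), 1:40)
  expect_length(region_channels(lay, hemisphere = "L"), 20L)
  expect_length(intersect(region_channels(lay, "PFC-left"),
                          region_channels(lay, hemisphere = "R")), 0L)
})

test_that("state-label conventions map sides to codes", {
  expect_equal(unname(state_codes()), 0:2)
  expect_equal(side_to_code("right"), 1L)
  expect_equal(side_to_code("left"), 2L)
  expect_error(side_to_code("up"), "left|right")
  expect_equal(collapse_binary(c(0L, 1L, 2L, 0L)), c(0L, 1L, 1L, 0L))
  expect_error(collapse_binary(c(0L, 3L)), "codes")
})

test_that("layout can be overridden from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("channels:",
               unlist(lapply(1:4, function(i) c(
                 sprintf("  - channel: %d", i),
                 sprintf("    emitter: %d", (i + 1) %/% 2),
                 sprintf("    detector: %d", i),
                 "    region: PFC-left",
                 "    hemisphere: L",
                 "    separation_cm: 2.5")))), path)
  lay <- layout_from_yaml(path)
  expect_equal(nrow(lay$channels), 4L)
  expect_true(all(lay$channels$separation_cm == 2.5))
  expect_equal(nrow(lay$emitters), 8L)  # defaults retained
})
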