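test_that("temperature trace follows the -2 C/s ramp to the click", {
  proto <- protocol_spec()
  fs <- 20
  # full ramp 32 -> 0 lasts 16 s
  tr <- temperature_trace(proto, 0, fs)
  expect_equal(tr$click - round(proto$baseline_s * fs), 16 * fs)
  # threshold 10 C: click (32-10)/2 = 11 s after ramp onset
  tr10 <- temperature_trace(proto, 10, fs)
  expect_equal(tr10$click - round(proto$baseline_s * fs), 11 * fs)
  expect_equal(tr10$temp[tr10$click], 10, tolerance = 1e-9)
  # degenerate: click immediately at ramp start
  tr32 <- temperature_trace(proto, 32, fs)
  expect_equal(tr32$click, round(proto$baseline_s * fs))
  expect_error(temperature_trace(proto, 40), "threshold")
})

test_that("default protocol labels exactly 100 pain samples per trial", {
  sim <- small_subject(n_trials = 4L)
  expect_equal(sum(sim$truth$state > 0), 4L * 100L)
  # label conservation: pain + no-pain = total
  expect_equal(sum(sim$truth$state > 0) + sum(sim$truth$state == 0),
               length(sim$truth$state))
  # pain windows sit right after each click
  for (ck in sim$truth$clicks) {
    expect_true(all(sim$truth$state[ck:(ck + 99)] > 0))
    expect_equal(sim$truth$state[ck - 1], 0L)
  }
})

test_that("simulation is bit-deterministic given the seed", {
  a <- simulate_subject(protocol_spec(n_trials = 2L), seed = 99)
  b <- simulate_subject(protocol_spec(n_trials = 2L), seed = 99)
  expect_identical(a$recording$intensity, b$recording$intensity)
  expect_identical(a$truth$state, b$truth$state)
  c <- simulate_subject(protocol_spec(n_trials = 2L), seed = 100)
  expect_false(identical(a$recording$intensity, c$recording$intensity))
})

test_that("zero-amplitude, zero-noise simulation is flat", {
  hemo <- quiet_hemo(pfc_amp = 0, s1_amp1 = 0, s1_amp2 = 0)
  sim <- small_subject(n_trials = 2L, hemo = hemo)
  expect_true(all(sim$recording$intensity == sim$recording$intensity[1]))
  hb <- preprocess_pipeline(sim$recording, fspec = NULL, qc = FALSE)
  expect_equal(max(abs(hb$data)), 0)
})

test_that("responses are lateralized: S1 contralateral, PFC bilateral", {
  for (side in c("left", "right")) {
    sim <- small_subject(n_trials = 2L, side = side, hemo = quiet_hemo())
    lay <- sim$recording$layout
    contra <- if (side == "left") "S1-right" else "S1-left"
    ipsi <- if (side == "left") "S1-left" else "S1-right"
    hb <- sim$truth$hb_um
    expect_gt(max(abs(hb[, region_channels(lay, contra), 1])), 0)
    expect_equal(max(abs(hb[, region_channels(lay, ipsi), 1])), 0)
    l <- hb[, region_channels(lay, "PFC-left"), 1]
    r <- hb[, region_channels(lay, "PFC-right"), 1]
    expect_equal(l, r, tolerance = 1e-9)
    # HbR anticorrelated at the configured ratio
    expect_equal(hb[, , 2], -hb[, , 1] / 3, tolerance = 1e-12)
  }
})

test_that("cohort simulation respects sides, ids and trial counts", {
  proto <- protocol_spec(n_trials = 2L)
  cohort <- simulate_cohort(2, sides = c("left", "right"), seed = 4,
                            protocol = proto)
  codes <- unlist(lapply(cohort, function(s) unique(s$truth$state)))
  expect_true(all(c(1L, 2L) %in% codes))
  expect_error(simulate_cohort(2, seed = 4, subject_ids = c("a", "a")),
               "unique")
  expect_error(protocol_spec(n_trials = 0L), "n_trials")
})

test_that("click-miss probability drops pain labels for missed trials", {
  proto <- protocol_spec(n_trials = 20L, click_miss_prob = 0.1)
  sim <- simulate_subject(proto, seed = 17)
  n_clicked <- sum(!is.na(sim$truth$clicks))
  expect_lt(n_clicked, 20L)
  expect_equal(sum(sim$truth$state > 0), n_clicked * 100L)
})
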