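test_that("optical density matches the log-ratio definition", {
  rec <- tiny_recording(n = 220, cardiac = FALSE)
  # constant intensity -> all-zero OD
  expect_equal(max(abs(intensity_to_od(rec))), 0)
  # I = I0 * exp(-1) at one sample -> OD = 1 there
  rec2 <- rec
  rec2$intensity[215, 7, 2] <- exp(-1)
  od <- intensity_to_od(rec2, baseline_window = c(1L, 200L))
  expect_equal(od[215, 7, 2], 1, tolerance = 1e-9)
  # brute-force recomputation on a random recording
  rec3 <- tiny_recording(n = 240, seed = 8)
  od3 <- intensity_to_od(rec3, baseline_window = c(1L, 100L))
  ch <- 13; wl <- 1
  i0 <- mean(rec3$intensity[1:100, ch, wl])
  expect_equal(od3[, ch, wl], -log(rec3$intensity[, ch, wl] / i0),
               tolerance = 1e-12)
  bad <- rec
  bad$intensity[1, 1, 1] <- 0
  expect_error(intensity_to_od(bad), "positive")
})

test_that("band-pass keeps the hemodynamic band and rejects cardiac", {
  fs <- 20
  n <- 4000
  tt <- seq_len(n) / fs
  rms <- function(x) sqrt(mean(x^2))
  # pure cardiac sinusoid: strongly attenuated
  cardiac <- sin(2 * pi * 1 * tt)
  expect_lt(rms(bandpass(cardiac, fs = fs)), 0.1 * rms(cardiac))
  # in-band sinusoid: preserved
  slow <- sin(2 * pi * 0.05 * tt)
  expect_gt(rms(bandpass(slow, fs = fs)), 0.9 * rms(slow))
  # DC is below the band
  expect_lt(rms(bandpass(rep(1, n), fs = fs)), 0.05)
  expect_error(bandpass(1:5, fs = fs), "too short")
})

test_that("analytic filter response matches empirically measured gains", {
  fs <- 20
  n <- 8000
  tt <- seq_len(n) / fs
  for (f in c(0.05, 0.1, 0.5, 1)) {
    x <- sin(2 * pi * f * tt)
    y <- bandpass(x, fs = fs)
    core <- 2000:6000  # avoid edges
    gain_meas <- sqrt(mean(y[core]^2) / mean(x[core]^2))
    gain_pred <- bandpass_response(f, fs = fs)
    expect_equal(gain_meas, gain_pred, tolerance = 0.02)
  }
})

test_that("MBLL inverts the forward model and is linear in DPF", {
  params <- mbll_params()
  # zero OD -> zero concentrations
  od0 <- array(0, c(5, 40, 2))
  expect_equal(max(abs(mbll(od0, params))), 0)
  # forward-inverse round trip to 1e-9
  withr::with_seed(2, {
    hb <- array(rnorm(50 * 40 * 2), c(50, 40, 2))
  })
  od <- forward_mbll(hb, params)
  expect_equal(mbll(od, params), hb, tolerance = 1e-9)
  # doubling both DPFs halves the recovered concentrations
  params2 <- mbll_params(dpf = 12)
  expect_equal(mbll(od, params2), hb / 2, tolerance = 1e-9)
  # singular extinction matrix is rejected
  expect_error(mbll_params(extinction = matrix(1, 2, 2)), "singular")
})

test_that("two-step quality control flags dead channels", {
  rec <- tiny_recording(n = 700, cardiac = TRUE)
  qc <- quality_control(rec)
  expect_equal(nrow(qc), 40L)
  expect_true(all(qc$pass))
  # clip one channel to a constant: CV ~ 0 fails step 1, no cardiac peak
  rec$intensity[, 11, ] <- 1
  qc2 <- quality_control(rec)
  expect_false(qc2$step1[11])
  expect_false(qc2$pass[11])
  expect_true(all(qc2$pass[-11]))
  expect_error(quality_control(tiny_recording(n = 100)), "30 s")
})

test_that("pipeline composes QC, OD, band-pass and MBLL in order", {
  sim <- small_subject(n_trials = 2L)
  rec <- sim$recording
  hb <- preprocess_pipeline(rec)
  manual <- mbll(bandpass(intensity_to_od(rec), filter_spec(),
                          rec$sampling_rate), mbll_params())
  expect_identical(hb$data, manual)
  expect_identical(hb$quality_mask, quality_control(rec)$pass)
  expect_identical(hb$events, rec$events)
  # events are not required for preprocessing
  rec$events <- empty_events()
  expect_s3_class(preprocess_pipeline(rec, qc = FALSE), "hb_timeseries")
})

test_that("pipeline is linear in the optical-density signal", {
  sim <- small_subject(n_trials = 2L, hemo = quiet_hemo())
  rec <- sim$recording
  od <- intensity_to_od(rec)
  rec3 <- rec
  rec3$intensity <- exp(-3 * od)  # OD scaled by 3, same baseline
  hb1 <- preprocess_pipeline(rec, qc = FALSE)
  hb3 <- preprocess_pipeline(rec3, qc = FALSE)
  # the narrow-band IIR filter limits achievable agreement to ~1e-6
  expect_equal(hb3$data, 3 * hb1$data, tolerance = 1e-4)
})

test_that("noise-free simulation is recovered by the pipeline", {
  res <- experiment_forward_inverse(seed = 6, n_trials = 4L)
  expect_lt(res$rel_err_exact, 1e-9)
  expect_lt(res$rel_err_filtered, 0.01)
  expect_gt(res$min_correlation, 0.95)
})
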