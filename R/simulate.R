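# Synthetic fNIRS generator: emulates a descending cold-stimulation
# protocol on a dental-pain cohort. Each trial holds the thermode at a
# 32 C baseline, ramps down at -2 C/s until the subject clicks at their
# pain threshold, then keeps recording through the post-click window.
# Expectation-evoked bilateral PFC responses precede the click; a two-peak
# response appears in S1 contralateral to the stimulated side. Injected
# hemodynamics are pushed through the forward Beer-Lambert model and
# physiological noise is added to the optical signal.

#' Cold-stimulation protocol specification
#'
#' @param n_trials Number of stimulation trials (default 20).
#' @param start_temp Baseline thermode temperature, degrees C (default 32).
#' @param ramp_rate Cooling rate, degrees C per second (default -2).
#' @param threshold_mean,threshold_sd Cohort distribution (normal, degrees
#'   C) of per-subject pain-threshold temperatures. Defaults 5 and 3:
#'   hypersensitive subjects tolerate most of the 32->0 ramp.
#' @param trial_jitter_sd Trial-to-trial jitter of the threshold within a
#'   subject, degrees C (default 0.5).
#' @param baseline_s Pre-ramp baseline per trial, seconds (default 12;
#'   absorbs the inter-trial interval, so `iti_s` defaults to 0).
#' @param post_click_s Recording retained after the click, seconds
#'   (default 12).
#' @param iti_s Extra inter-trial gap, seconds (default 0).
#' @param pain_label_s Seconds after the threshold click labeled as pain
#'   (default 5, i.e. 100 samples at 20 Hz per trial).
#' @param click_miss_prob Probability that a trial ends without a click
#'   (ramp runs to 0 C, no pain labels; default 0).
#' @return A `protocol_spec` list.
#' @export
protocol_spec <- function(n_trials = 20L, start_temp = 32, ramp_rate = -2,
                          threshold_mean = 5, threshold_sd = 3,
                          trial_jitter_sd = 0.5,
                          baseline_s = 12, post_click_s = 12, iti_s = 0,
                          pain_label_s = 5, click_miss_prob = 0) {
  assert_that(n_trials >= 1, "n_trials must be >= 1")
  assert_that(start_temp > 0, "start_temp must be positive")
  assert_that(ramp_rate < 0, "ramp_rate must be negative (cooling)")
  assert_that(pain_label_s > 0, "pain_label_s must be positive")
  assert_that(post_click_s >= pain_label_s,
              "post_click_s must cover the pain label window")
  assert_that(click_miss_prob >= 0 && click_miss_prob <= 1,
              "click_miss_prob must be a probability")
  structure(as.list(environment()), class = "protocol_spec")
}

#' Hemodynamic response specification
#'
#' Shapes the injected responses: an expectation-evoked bilateral
#' prefrontal (PFC) response beginning before the threshold click, and a
#' two-peak response confined to the primary somatosensory cortex (S1)
#' contralateral to the stimulated side. Responses use a canonical
#' double-gamma hemodynamic response function; HbR is anticorrelated with
#' HbO by a fixed negative ratio. Physiological noise comprises cardiac,
#' respiratory and Mayer-wave oscillations (subject-random phases), white
#' noise, and a linear drift, all expressed in optical-density units.
#'
#' @param pfc_amp Peak PFC HbO amplitude, uM (bilateral; default 0.5).
#' @param expectation_lag_s Onset of the PFC response before the click,
#'   seconds (default 4).
#' @param s1_amp1,s1_amp2 Peak amplitudes of the two contralateral S1
#'   responses, uM (defaults 0.8 and 0.6).
#' @param peak_sep_s Separation of the two S1 peaks, seconds (default 4).
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio Double-gamma parameters:
#'   response peak (6 s), undershoot peak (16 s), undershoot ratio (1/6).
#' @param hbr_ratio HbR/HbO amplitude ratio, negative (default -1/3).
#' @param cardiac_hz,cardiac_amp Cardiac oscillation (1.1 Hz, 0.005 OD).
#' @param resp_hz,resp_amp Respiratory oscillation (0.25 Hz, 0.003 OD).
#' @param mayer_hz,mayer_amp Mayer waves (0.1 Hz, 0.004 OD).
#' @param white_sd White-noise SD, OD units (default 0.003).
#' @param drift_per_s Linear drift slope, OD/s (default 1e-5).
#' @param i0 Mean raw-intensity level, arbitrary light units (default 1).
#' @return A `hemo_response_spec` list.
#' @export
hemo_response_spec <- function(pfc_amp = 0.5, expectation_lag_s = 4,
                               s1_amp1 = 0.8, s1_amp2 = 0.6,
                               peak_sep_s = 4,
                               hrf_peak_s = 6, hrf_undershoot_s = 16,
                               hrf_ratio = 1 / 6,
                               hbr_ratio = -1 / 3,
                               cardiac_hz = 1.1, cardiac_amp = 0.005,
                               resp_hz = 0.25, resp_amp = 0.003,
                               mayer_hz = 0.1, mayer_amp = 0.004,
                               white_sd = 0.003, drift_per_s = 1e-5,
                               i0 = 1.0) {
  spec <- mget(names(formals(hemo_response_spec)))
  assert_that(all(is.finite(unlist(spec))), "hemo parameters must be finite")
  assert_that(hbr_ratio < 0, "hbr_ratio must be negative (anticorrelated)")
  assert_that(all(c(cardiac_amp, resp_amp, mayer_amp, white_sd) >= 0),
              "noise amplitudes must be >= 0")
  structure(spec, class = "hemo_response_spec")
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time points, seconds (>= 0).
#' @param peak_s Peak time of the positive lobe (default 6 s).
#' @param undershoot_s Peak time of the undershoot (default 16 s).
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @return Kernel values, scaled so the positive peak equals 1.
#' @export
double_gamma_hrf <- function(t, peak_s = 6, undershoot_s = 16,
                             ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s, rate = 1)
  peak <- stats::dgamma(peak_s - 1, shape = peak_s, rate = 1) -
    ratio * stats::dgamma(peak_s - 1, shape = undershoot_s, rate = 1)
  h / peak
}

#' Thermode temperature trace for one trial
#'
#' Linear ramp from the start temperature at the protocol's (negative)
#' ramp rate, truncated at the subject's threshold (the click), then a
#' return to baseline over the post-click window.
#'
#' @param protocol A [protocol_spec()].
#' @param threshold_temp Temperature at which the subject clicks, degrees C.
#' @param fs Sampling rate, Hz (default 20).
#' @return List with `temp` (degrees C per sample over the trial epoch),
#'   `click` (sample index of the click within the epoch, `NA` if
#'   `threshold_temp` is `NA`), and `n` (epoch length in samples).
#' @export
temperature_trace <- function(protocol, threshold_temp, fs = 20) {
  p <- protocol
  missed <- is.na(threshold_temp)
  stop_temp <- if (missed) 0 else threshold_temp
  assert_that(stop_temp >= 0 && stop_temp <= p$start_temp,
              "threshold temperature must lie in [0, start_temp]")
  ramp_s <- (p$start_temp - stop_temp) / abs(p$ramp_rate)
  n_base <- as.integer(round(p$baseline_s * fs))
  n_ramp <- as.integer(round(ramp_s * fs))
  n_post <- as.integer(round((p$post_click_s + p$iti_s) * fs))
  temp <- c(
    rep(p$start_temp, n_base),
    p$start_temp + p$ramp_rate * seq_len(n_ramp) / fs,
    # linear rewarm back to baseline across the post-click window
    stop_temp + (p$start_temp - stop_temp) * seq_len(n_post) / n_post
  )
  click <- if (missed) NA_integer_ else n_base + n_ramp
  list(temp = temp, click = click, n = n_base + n_ramp + n_post)
}

# Place HRF-convolved responses: add amp * kernel starting at each impulse
# sample, truncated to the recording; impulses before sample 1 contribute
# their tail.
inject_kernel <- function(n, at, amp, kernel) {
  y <- numeric(n)
  nk <- length(kernel)
  for (i in which(!is.na(at))) {
    a <- at[i]
    koff <- if (a < 1L) 1L - a else 0L
    a <- max(a, 1L)
    len <- min(nk - koff, n - a + 1L)
    if (len > 0) {
      idx <- a:(a + len - 1L)
      y[idx] <- y[idx] + amp[i] * kernel[(koff + 1L):(koff + len)]
    }
  }
  y
}

#' Simulate one subject's recording
#'
#' Generates a continuous dual-wavelength raw-intensity recording for one
#' subject under the cold-stimulation protocol, together with per-sample
#' ground-truth state labels and the injected hemoglobin time courses.
#' Samples within `pain_label_s` seconds after each threshold click are
#' labeled as pain on the stimulated side (code 1 right, 2 left);
#' everything else is no-pain (code 0).
#'
#' @param protocol A [protocol_spec()].
#' @param hemo A [hemo_response_spec()].
#' @param side Stimulated side, `"left"` or `"right"`.
#' @param seed Integer seed; all randomness derives from it.
#' @param subject_id Subject identifier (default `"sim01"`).
#' @param fs Sampling rate, Hz (default 20).
#' @param params Beer-Lambert constants shared with the preprocessing
#'   chain ([mbll_params()]).
#' @return List with `recording` (a [recording()]) and `truth` (a
#'   `ground_truth` list: `state` per-sample codes, `clicks` per-trial
#'   click samples, `side`, `threshold_temps`, `trial_index` per-sample
#'   trial membership, `hb_um` the injected `time x 40 x 2` hemoglobin
#'   array, `temperature` the thermode trace).
#' @export
simulate_subject <- function(protocol = protocol_spec(),
                             hemo = hemo_response_spec(),
                             side = "left", seed = 1L,
                             subject_id = "sim01", fs = 20,
                             params = mbll_params()) {
  assert_that(side %in% c("left", "right"), "side must be 'left' or 'right'")
  layout <- default_layout()
  nch <- nrow(layout$channels)
  with_seed(seed, {
    subj_thr <- stats::rnorm(1, protocol$threshold_mean,
                             protocol$threshold_sd)
    subj_thr <- min(max(subj_thr, 0.5), protocol$start_temp - 1)
    trial_thr <- subj_thr +
      stats::rnorm(protocol$n_trials, 0, protocol$trial_jitter_sd)
    trial_thr <- pmin(pmax(trial_thr, 0.1), protocol$start_temp - 0.1)
    if (protocol$click_miss_prob > 0) {
      missed <- stats::runif(protocol$n_trials) < protocol$click_miss_prob
      trial_thr[missed] <- NA
    }
    if (any(!is.na(trial_thr) &
            (trial_thr <= 0 | trial_thr >= protocol$start_temp))) {
      # guarded above by pmin/pmax; defensive for user-supplied specs
      stop_config("trial threshold temperature outside (0, start_temp)")
    }

    traces <- lapply(trial_thr, function(th)
      temperature_trace(protocol, th, fs))
    epoch_n <- vapply(traces, `[[`, 0L, "n")
    offsets <- cumsum(c(0L, epoch_n[-length(epoch_n)]))
    n <- sum(epoch_n)

    onsets <- offsets + round(protocol$baseline_s * fs)  # ramp start
    clicks <- offsets + vapply(traces, function(tr)
      if (is.na(tr$click)) NA_integer_ else tr$click, 0L)
    temperature <- unlist(lapply(traces, `[[`, "temp"))

    # --- ground-truth labels -------------------------------------------
    state <- integer(n)
    pain_n <- round(protocol$pain_label_s * fs)
    code <- side_to_code(side)
    for (ck in clicks[!is.na(clicks)]) {
      idx <- ck:min(ck + pain_n - 1L, n)
      state[idx] <- code
    }
    trial_index <- rep(seq_len(protocol$n_trials), epoch_n)

    # --- injected hemodynamics -----------------------------------------
    kernel_t <- seq(0, 32, by = 1 / fs)
    kernel <- double_gamma_hrf(kernel_t, hemo$hrf_peak_s,
                               hemo$hrf_undershoot_s, hemo$hrf_ratio)
    ok <- !is.na(clicks)
    pfc_at <- clicks[ok] - round(hemo$expectation_lag_s * fs)
    pfc_course <- inject_kernel(n, pfc_at, rep(hemo$pfc_amp, sum(ok)),
                                kernel)
    s1_course <- inject_kernel(
      n,
      c(clicks[ok], clicks[ok] + round(hemo$peak_sep_s * fs)),
      c(rep(hemo$s1_amp1, sum(ok)), rep(hemo$s1_amp2, sum(ok))),
      kernel)

    contra <- if (side == "left") "S1-right" else "S1-left"
    hb_um <- array(0, c(n, nch, 2L))
    pfc_ch <- region_channels(layout, c("PFC-left", "PFC-right"))
    s1_ch <- region_channels(layout, contra)
    hb_um[, pfc_ch, 1L] <- pfc_course
    hb_um[, s1_ch, 1L] <- hb_um[, s1_ch, 1L] + s1_course
    hb_um[, , 2L] <- hemo$hbr_ratio * hb_um[, , 1L]

    # --- forward optics + noise ----------------------------------------
    od <- forward_mbll(hb_um, params)
    tt <- seq_len(n) / fs
    noise <- array(0, c(n, nch, 2L))
    for (k in 1:2) {
      phases <- matrix(stats::runif(3 * nch, 0, 2 * pi), 3, nch)
      gains <- matrix(stats::runif(3 * nch, 0.8, 1.2), 3, nch)
      osc <- hemo$cardiac_amp *
        sin(outer(tt, rep(2 * pi * hemo$cardiac_hz, nch)) +
              rep(phases[1, ], each = n)) * rep(gains[1, ], each = n) +
        hemo$resp_amp *
        sin(outer(tt, rep(2 * pi * hemo$resp_hz, nch)) +
              rep(phases[2, ], each = n)) * rep(gains[2, ], each = n) +
        hemo$mayer_amp *
        sin(outer(tt, rep(2 * pi * hemo$mayer_hz, nch)) +
              rep(phases[3, ], each = n)) * rep(gains[3, ], each = n)
      wn <- matrix(stats::rnorm(n * nch, 0, hemo$white_sd), n, nch)
      drift <- outer(tt, stats::runif(nch, -1, 1) * hemo$drift_per_s)
      noise[, , k] <- osc + wn + drift  # OD units
    }
    intensity <- hemo$i0 * exp(-(od + noise))

    events <- data.frame(
      trial = seq_len(protocol$n_trials) - 1L,
      onset = as.integer(onsets),
      click = as.integer(clicks),
      side = side,
      threshold_temp = ifelse(is.na(trial_thr), NA_real_, trial_thr),
      stringsAsFactors = FALSE
    )
    rec <- recording(subject_id, intensity, sampling_rate = fs,
                     events = events, layout = layout)
    truth <- structure(
      list(state = state, clicks = clicks, side = side,
           threshold_temps = trial_thr, trial_index = trial_index,
           hb_um = hb_um, temperature = temperature),
      class = "ground_truth")
    list(recording = rec, truth = truth)
  })
}

#' Simulate a cohort of subjects
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param sides Stimulated side per subject; recycled. Default alternates
#'   left/right.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param protocol,hemo,fs,params As in [simulate_subject()].
#' @param subject_ids Optional character vector of unique ids.
#' @return List of `list(recording, truth)` per subject.
#' @export
simulate_cohort <- function(n_subjects, sides = NULL, seed = 1L,
                            protocol = protocol_spec(),
                            hemo = hemo_response_spec(), fs = 20,
                            params = mbll_params(), subject_ids = NULL) {
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  if (is.null(sides)) sides <- rep(c("left", "right"),
                                   length.out = n_subjects)
  sides <- rep_len(sides, n_subjects)
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("sim%02d", seq_len(n_subjects))
  }
  assert_that(!anyDuplicated(subject_ids),
              "subject ids must be unique")
  seeds <- derive_seeds(seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(protocol, hemo, sides[i], seeds[i],
                     subject_id = subject_ids[i], fs = fs, params = params)
  })
}
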