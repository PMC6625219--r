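# Shared fixtures, all built in code at test time.

# A tiny valid recording: n samples of positive intensity with optional
# sinusoidal cardiac structure so it can pass quality control.
tiny_recording <- function(n = 700, fs = 20, cardiac = TRUE, seed = 1) {
  withr::with_seed(seed, {
    tt <- seq_len(n) / fs
    base <- array(1, c(n, 40L, 2L))
    if (cardiac) {
      osc <- 0.01 * sin(2 * pi * 1.1 * tt) + 0.002 * rnorm(n)
      base <- base * exp(-array(osc, c(n, 40L, 2L)))
    }
    recording("toy", base, sampling_rate = fs)
  })
}

# Small noise-free simulated subject (shared across expensive tests).
quiet_hemo <- function(...) {
  hemo_response_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0,
                     white_sd = 0, drift_per_s = 0, ...)
}

small_subject <- function(n_trials = 4L, seed = 5, side = "left",
                          hemo = hemo_response_spec()) {
  simulate_subject(protocol_spec(n_trials = n_trials), hemo, side = side,
                   seed = seed)
}

# Separable two-blob cube data for classifier checks.
toy_blobs <- function(n = 120, shape = c(8L, 8L, 2L), sep = 1.5,
                      seed = 3, classes = 2L) {
  withr::with_seed(seed, {
    y <- rep(seq_len(classes) - 1L, length.out = n)
    x <- array(stats::rnorm(n * prod(shape), mean = rep(y * sep,
                                                        prod(shape))),
               c(n, shape))
    list(x = x, labels = y)
  })
}
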