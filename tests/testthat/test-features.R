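make_toy_hb <- function(n = 200, seed = 1, fs = 20) {
  withr::with_seed(seed, {
    hb_timeseries("toy", array(rnorm(n * 40 * 2), c(n, 40L, 2L)),
                  sampling_rate = fs)
  })
}

test_that("type-I cube counting and labeling follow the window contract", {
  hb <- make_toy_hb(100)
  state <- integer(100)
  state[80:95] <- 1L
  set <- make_type1_cubes(hb, state, stride = 1L)
  expect_equal(n_cubes(set), 61L)  # anchors 40..100
  expect_equal(range(set$anchors$anchor), c(40L, 100L))
  # label is the state at the anchor (last sample of the window)
  expect_equal(set$anchors$label, state[40:100])
  x <- cube_array(set, 1:3)
  expect_equal(dim(x), c(3L, 40L, 40L, 2L))
  expect_equal(x[2, , , ], hb$data[2:41, , ], tolerance = 0)
  expect_error(make_type1_cubes(hb, state, stride = 0L), "stride")
  # constant series -> every cube identical
  hbc <- hb
  hbc$data[] <- 2
  setc <- make_type1_cubes(hbc, state)
  xc <- cube_array(setc, c(1, 30))
  expect_identical(xc[1, , , ], xc[2, , , ])
})

test_that("type-II cubes concatenate two history blocks lag apart", {
  hb <- make_toy_hb(300)
  state <- integer(300)
  set <- make_type2_cubes(hb, state, lag = 160L)
  x <- cube_array(set, 1L)
  expect_equal(dim(x), c(1L, 80L, 40L, 2L))
  a <- set$anchors$anchor[1]
  expect_equal(a, 200L)  # first anchor with full 10-s history
  expect_equal(x[1, 1:40, , ], hb$data[(a - 199):(a - 160), , ])
  expect_equal(x[1, 41:80, , ], hb$data[(a - 39):a, , ])
  expect_error(make_type2_cubes(hb, state, lag = 39L), "overlap")
  # constant series: block A equals block B
  hbc <- hb
  hbc$data[] <- 1.5
  xc <- cube_array(make_type2_cubes(hbc, state), 1L)
  expect_identical(xc[1, 1:40, , ], xc[1, 41:80, , ])
})

test_that("cubes are causal: no window reaches past its anchor", {
  hb <- make_toy_hb(250, seed = 11)
  state <- integer(250)
  set1 <- make_type1_cubes(hb, state)
  set2 <- make_type2_cubes(hb, state, lag = 60L)
  withr::with_seed(12, {
    for (set in list(set1, set2)) {
      idx <- sample(n_cubes(set), 5)
      before <- cube_array(set, idx)
      for (k in seq_along(idx)) {
        a <- set$anchors$anchor[idx[k]]
        if (a >= nrow(hb$data)) next
        hb2 <- hb
        hb2$data[(a + 1):nrow(hb2$data), , ] <- 999
        set_mod <- set
        set_mod$hb[[1]] <- hb2
        expect_identical(cube_array(set_mod, idx[k]),
                         before[k, , , , drop = FALSE])
      }
    }
  })
})

test_that("streaming normalization matches a brute-force rolling mean", {
  withr::with_seed(3, x <- matrix(5 + rnorm(400), 200, 2))
  out <- stream_normalize_series(x, window_s = 2, fs = 20)
  # independent recomputation
  w <- 40L
  brute <- x
  for (t in seq_len(nrow(x))) {
    win <- max(1L, t - w + 1L):t
    m <- colMeans(x[win, , drop = FALSE])
    brute[t, ] <- x[t, ] / (m + 1e-9 * sign(m))
  }
  brute <- pmin(pmax(brute, -10), 10)
  expect_equal(out, brute, tolerance = 1e-12)
  # per-sample state machine agrees with the batch path
  st <- stream_norm_state(2L, window_s = 2, fs = 20)
  online <- matrix(NA_real_, nrow(x), 2)
  for (t in seq_len(nrow(x))) {
    step <- stream_normalize(x[t, ], st)
    online[t, ] <- step$value
    st <- step$state
  }
  expect_equal(online, out, tolerance = 1e-12)
})

test_that("normalization is scale-invariant and unit on constants", {
  x <- matrix(3, 100, 4)
  expect_equal(stream_normalize_series(x, window_s = 1, fs = 20),
               matrix(1, 100, 4), tolerance = 1e-8)
  withr::with_seed(4, y <- matrix(2 + runif(200), 100, 2))
  a <- stream_normalize_series(y, window_s = 1, fs = 20)
  b <- stream_normalize_series(10 * y, window_s = 1, fs = 20)
  expect_equal(a, b, tolerance = 1e-7)
  # recording-level normalization keeps intensities positive
  rec <- tiny_recording(n = 100)
  nrec <- normalize_recording(rec)
  expect_true(all(nrec$intensity > 0))
  expect_equal(mean(nrec$intensity), 1, tolerance = 0.01)
})

test_that("merge_and_permute pools subjects and is seed-deterministic", {
  hb1 <- make_toy_hb(150, seed = 21)
  hb2 <- make_toy_hb(150, seed = 22)
  hb2$subject_id <- "toy2"
  s1 <- make_type1_cubes(hb1, rep(c(0L, 2L), c(100, 50)))
  s2 <- make_type1_cubes(hb2, rep(c(0L, 1L), c(100, 50)))
  m <- merge_and_permute(list(s1, s2), seed = 7)
  expect_setequal(unique(m$anchors$label), c(0L, 1L, 2L))
  expect_equal(n_cubes(m), n_cubes(s1) + n_cubes(s2))  # keep_prob 1
  m2 <- merge_and_permute(list(s1, s2), seed = 7, keep_prob = 0.5)
  m3 <- merge_and_permute(list(s1, s2), seed = 7, keep_prob = 0.5)
  expect_identical(m2$anchors, m3$anchors)
  expect_lt(n_cubes(m2), n_cubes(m))
  t2 <- make_type2_cubes(hb2, rep(0L, 150), lag = 60L)
  expect_error(merge_and_permute(list(s1, t2)), "mixed")
  expect_error(merge_and_permute(list(s1, s1)), "duplicate")
})

test_that("class weights implement the 10:1 and inverse-frequency schemes", {
  hb <- make_toy_hb(139)
  # anchors 40..139: 50 no-pain then 50 pain cubes (balanced)
  set <- make_type1_cubes(hb, rep(c(0L, 1L), c(89, 50)))
  expect_equal(class_weights(set, "paper-10:1"), c("0" = 1, "1" = 10))
  w <- class_weights(set, "inverse-frequency")
  expect_equal(unname(w), c(1, 1))
  # published 3-class counts: 26,820 / 2000 / 2000
  counts <- c(26820, 2000, 2000)
  wif <- counts^-1 / min(counts^-1)
  expect_equal(round(max(wif), 2), 13.41)
  one <- make_type1_cubes(hb, rep(0L, 139))
  expect_error(class_weights(one, "inverse-frequency"), "2 classes")
})

test_that("oversampling balances to the majority count, reproducibly", {
  hb <- make_toy_hb(240, seed = 30)
  set <- make_type1_cubes(hb, rep(c(0L, 1L), c(180, 60)))
  os <- oversample(set, seed = 5)
  expect_equal(unname(class_counts(os)), c(141L, 141L))
  os2 <- oversample(set, seed = 5)
  expect_identical(os$anchors, os2$anchors)
  # balanced input unchanged (anchors 40..239: 100 cubes per class)
  hb2 <- make_toy_hb(239, seed = 31)
  bal <- make_type1_cubes(hb2, rep(c(0L, 1L), c(139, 100)))
  expect_identical(oversample(bal, seed = 1)$anchors, bal$anchors)
})
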