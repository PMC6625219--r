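# Feature cubes: sliding-window tensors of shape T x 40 x 2
# (time samples x channels x [HbO, HbR]) fed to the classifiers.
#   type I  : T = 40, one 2-second history block ending at the anchor.
#   type II : T = 80, two 2-second blocks -- the block ending at the anchor
#             and a second block `lag` samples earlier (default 8 s), so
#             the cube spans up to 10 s of history and captures the
#             expectation phase as well as the pain phase.
# A cube_set stores anchors and labels; tensors are materialized on demand
# with cube_array(), so million-cube sets stay cheap.

#' Assemble type-I feature cubes (single 2-s history block)
#'
#' For each anchor sample `a` (stepping by `stride`), the cube covers the
#' 40 samples ending at `a` (2 s at 20 Hz) over all 40 channels and both
#' chromophores; its label is the ground-truth state at the anchor (the
#' most recent sample in the window). Anchors with incomplete history are
#' skipped, so a series of `N` samples yields `N - 39` cubes at stride 1.
#'
#' @param hb An [hb_timeseries()].
#' @param truth Ground truth from [simulate_subject()], or an integer
#'   vector of per-sample state codes.
#' @param stride Anchor step in samples (default 1).
#' @return A `cube_set`.
#' @export
make_type1_cubes <- function(hb, truth, stride = 1L) {
  make_cubes(hb, truth, type = 1L, stride = stride, lag = 0L)
}

#' Assemble type-II feature cubes (two split 2-s history blocks)
#'
#' Each cube concatenates, along the time axis, block A = the 40 samples
#' ending `lag` samples before the anchor, and block B = the 40 samples
#' ending at the anchor (shape 80 x 40 x 2). With the default
#' `lag = 160` (8 s) the total history span is 10 s, so block A sees the
#' expectation-evoked prefrontal response while block B sees the pain
#' phase. `lag` must be at least 40 samples or the blocks would overlap.
#'
#' @inheritParams make_type1_cubes
#' @param lag Samples between the two block ends (default 160 = 8 s).
#' @return A `cube_set`.
#' @export
make_type2_cubes <- function(hb, truth, lag = 160L, stride = 1L) {
  assert_that(lag >= 40L, "lag must be >= 40 samples (blocks would overlap)")
  make_cubes(hb, truth, type = 2L, stride = stride, lag = as.integer(lag))
}

make_cubes <- function(hb, truth, type, stride, lag) {
  validate_hb(hb)
  assert_that(stride >= 1L, "stride must be >= 1")
  state <- if (is.list(truth)) truth$state else as.integer(truth)
  trial <- if (is.list(truth) && !is.null(truth$trial_index))
    truth$trial_index else rep(NA_integer_, length(state))
  n <- n_samples(hb)
  assert_that(length(state) == n,
              "ground truth length does not match the series")
  block <- 40L
  first <- if (type == 1L) block else lag + block
  assert_that(n >= first, "recording shorter than one cube")
  anchors <- seq.int(first, n, by = stride)
  cs <- structure(
    list(hb = stats::setNames(list(hb), hb$subject_id),
         anchors = data.frame(subject = hb$subject_id, anchor = anchors,
                              label = state[anchors], trial = trial[anchors],
                              stringsAsFactors = FALSE),
         cube_type = type, block = block, lag = if (type == 2L) lag else 0L,
         normalized = FALSE),
    class = "cube_set")
  cs
}

#' Number of cubes in a set
#' @param set A `cube_set`.
#' @return Integer count.
#' @export
n_cubes <- function(set) nrow(set$anchors)

#' Class counts of a cube set
#' @param set A `cube_set`.
#' @return Named integer vector of label counts (names are state codes).
#' @export
class_counts <- function(set) {
  tab <- table(factor(set$anchors$label, levels = sort(unique(set$anchors$label))))
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.cube_set <- function(x, ...) {
  tt <- if (x$cube_type == 1L) 40L else 80L
  cat(sprintf("<cube_set> %d cubes of %d x %d x 2 (type %s%s)%s\n",
              n_cubes(x), tt, nrow(x$hb[[1]]$layout$channels),
              c("I", "II")[x$cube_type],
              if (x$cube_type == 2L) sprintf(", lag %d", x$lag) else "",
              if (x$normalized) ", stream-normalized" else ""))
  print(class_counts(x))
  invisible(x)
}

cube_time_index <- function(set, anchors) {
  block <- set$block
  if (set$cube_type == 1L) {
    outer(anchors, (-block + 1L):0L, `+`)
  } else {
    cbind(outer(anchors - set$lag, (-block + 1L):0L, `+`),
          outer(anchors, (-block + 1L):0L, `+`))
  }
}

#' Materialize cube tensors
#'
#' Gathers the windowed tensors for a subset of cubes into a dense array.
#'
#' @param set A `cube_set`.
#' @param idx Cube indices (default all).
#' @return Array `n x T x channels x 2`.
#' @export
cube_array <- function(set, idx = seq_len(n_cubes(set))) {
  an <- set$anchors[idx, , drop = FALSE]
  tt <- if (set$cube_type == 1L) set$block else 2L * set$block
  nch <- nrow(set$hb[[1]]$layout$channels)
  out <- array(NA_real_, c(nrow(an), tt, nch, 2L))
  for (sid in unique(an$subject)) {
    rows <- which(an$subject == sid)
    hb <- set$hb[[sid]]
    d <- dim(hb$data)
    hmat <- matrix(hb$data, nrow = d[1])
    ti <- cube_time_index(set, an$anchor[rows])  # rows x T
    sl <- array(hmat[as.vector(ti), ], c(length(rows), tt, nch, 2L))
    out[rows, , , ] <- sl
  }
  out
}

#' Labels of a cube set
#' @param set A `cube_set`.
#' @param binary Collapse codes `{1, 2}` to 1 (pain) for the detection
#'   task.
#' @return Integer label vector.
#' @export
cube_labels <- function(set, binary = FALSE) {
  if (binary) collapse_binary(set$anchors$label) else set$anchors$label
}

# ---------------------------------------------------------------------------
# Streaming "divide by the mean" normalization

#' Initialize streaming-normalization state
#'
#' Real-time normalization divides each incoming sample, elementwise, by a
#' causally updated windowed mean of the same channel/chromophore,
#' eliminating baseline and gain differences when data from different
#' subjects are merged. The mean uses only samples up to and including the
#' current one. Because concentration *changes* can have near-zero
#' windowed means, the quotient is guarded by `eps` and clamped to
#' `[-clip, clip]`.
#'
#' @param n_series Number of parallel series (channels x chromophores).
#' @param window_s Mean window length, seconds (default 30).
#' @param fs Sampling rate, Hz (default 20).
#' @param eps Division guard added as `eps * sign(mean)` (default 1e-9).
#' @param clip Clamp for the normalized output (default 10).
#' @return A `stream_norm_state`.
#' @export
stream_norm_state <- function(n_series, window_s = 30, fs = 20,
                              eps = 1e-9, clip = 10) {
  assert_that(eps > 0, "eps must be positive")
  structure(
    list(window = as.integer(round(window_s * fs)), n_series = n_series,
         buffer = matrix(NA_real_, 0L, n_series), count = 0L,
         eps = eps, clip = clip),
    class = "stream_norm_state")
}

#' Normalize one streaming sample
#'
#' @param sample Numeric vector of length `state$n_series`.
#' @param state A [stream_norm_state()].
#' @return List with `value` (normalized vector) and `state` (advanced by
#'   one sample).
#' @export
stream_normalize <- function(sample, state) {
  assert_that(length(sample) == state$n_series,
              "sample length does not match normalization state")
  buf <- rbind(state$buffer, sample)
  if (nrow(buf) > state$window) buf <- buf[-1L, , drop = FALSE]
  m <- colMeans(buf)
  denom <- m + state$eps * ifelse(m >= 0, 1, -1)
  v <- pmin(pmax(sample / denom, -state$clip), state$clip)
  state$buffer <- buf
  state$count <- state$count + 1L
  list(value = v, state = state)
}

#' Normalize a whole series causally
#'
#' Batch equivalent of repeatedly calling [stream_normalize()]: row `t` of
#' the output depends only on rows `<= t` of the input, and the result is
#' identical to the one-sample-at-a-time loop.
#'
#' @param x Numeric matrix (time x series).
#' @param window_s,fs,eps,clip As in [stream_norm_state()].
#' @return Matrix of the same shape.
#' @export
stream_normalize_series <- function(x, window_s = 30, fs = 20,
                                    eps = 1e-9, clip = 10) {
  n <- nrow(x)
  w <- as.integer(round(window_s * fs))
  cs <- apply(x, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(x))
  lagged <- rbind(matrix(0, min(w, n), ncol(x)),
                  cs[seq_len(max(0L, n - w)), , drop = FALSE])
  counts <- pmin(seq_len(n), w)
  m <- (cs - lagged) / counts
  denom <- m + eps * ifelse(m >= 0, 1, -1)
  pmin(pmax(x / denom, -clip), clip)
}

#' Stream-normalize a hemoglobin time series
#'
#' Applies [stream_normalize_series()] across all channel/chromophore
#' series of an [hb_timeseries()]; used before merging subjects for the
#' localization task.
#'
#' @param hb An `hb_timeseries`.
#' @inheritParams stream_norm_state
#' @return An `hb_timeseries` with normalized (dimensionless) data.
#' @export
normalize_hb <- function(hb, window_s = 30, eps = 1e-9, clip = 10) {
  validate_hb(hb)
  d <- dim(hb$data)
  m <- stream_normalize_series(matrix(hb$data, nrow = d[1]),
                               window_s = window_s, fs = hb$sampling_rate,
                               eps = eps, clip = clip)
  hb$data <- array(m, d)
  hb
}

#' Stream-normalize a raw recording's intensities
#'
#' Applies the causal divide-by-the-mean scheme to the raw light
#' intensities, the best-conditioned target for this normalization: raw
#' intensity has a stable positive baseline, so the quotient hovers
#' around 1 and directly cancels gain and coupling differences between
#' subjects before any merging. The preprocessing chain runs unchanged on
#' the normalized recording.
#'
#' @param rec A [recording()].
#' @inheritParams stream_norm_state
#' @return A `recording` with normalized (dimensionless, ~1) intensities.
#' @export
normalize_recording <- function(rec, window_s = 30, eps = 1e-9, clip = 10) {
  validate_recording(rec)
  d <- dim(rec$intensity)
  m <- stream_normalize_series(matrix(rec$intensity, nrow = d[1]),
                               window_s = window_s, fs = rec$sampling_rate,
                               eps = eps, clip = clip)
  rec$intensity <- array(pmax(m, .Machine$double.eps), d)
  rec
}

# ---------------------------------------------------------------------------
# Merging, permutation, class balancing

#' Merge and permute cube sets
#'
#' Unions compatible cube sets (same cube type and geometry), shuffles the
#' cube order, and optionally subsamples cubes (random inclusion/
#' exclusion along the time course) with a seeded mask. Used to pool a
#' left-pain and a right-pain subject into one 3-class set.
#'
#' @param sets List of `cube_set`s with distinct subjects.
#' @param seed Integer seed for the permutation/mask.
#' @param keep_prob Probability of keeping each cube (default 1).
#' @return A merged `cube_set`.
#' @export
merge_and_permute <- function(sets, seed = 1L, keep_prob = 1) {
  assert_that(length(sets) >= 1, "need at least one cube set")
  types <- vapply(sets, `[[`, 0L, "cube_type")
  lags <- vapply(sets, `[[`, 0L, "lag")
  assert_that(length(unique(types)) == 1L && length(unique(lags)) == 1L,
              "cube sets have mixed cube types")
  subjects <- unlist(lapply(sets, function(s) names(s$hb)))
  assert_that(!anyDuplicated(subjects), "duplicate subjects across sets")
  merged <- sets[[1]]
  merged$hb <- do.call(c, lapply(sets, `[[`, "hb"))
  merged$anchors <- do.call(rbind, lapply(sets, `[[`, "anchors"))
  merged$normalized <- all(vapply(sets, `[[`, TRUE, "normalized"))
  n <- nrow(merged$anchors)
  with_seed(seed, {
    ord <- sample.int(n)
    keep <- stats::runif(n) <= keep_prob
  })
  merged$anchors <- merged$anchors[ord[keep[ord]], , drop = FALSE]
  rownames(merged$anchors) <- NULL
  merged
}

#' Class weights for training
#'
#' @param set A `cube_set` (or anything with >= 2 label classes via
#'   [cube_labels()]).
#' @param scheme `"paper-10:1"` -- the fixed pain:no-pain = 10:1
#'   reweighting used for the binary detection task; or
#'   `"inverse-frequency"` -- weights proportional to 1/count, normalized
#'   so the smallest weight is 1.
#' @param binary Compute on binary-collapsed labels (default `TRUE` for
#'   `"paper-10:1"`).
#' @return Named numeric vector mapping label code to weight.
#' @export
class_weights <- function(set, scheme = c("paper-10:1", "inverse-frequency"),
                          binary = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(binary)) binary <- scheme == "paper-10:1"
  labels <- cube_labels(set, binary = binary)
  counts <- table(labels)
  assert_that(length(counts) >= 2L,
              "class weights need at least 2 classes present")
  if (scheme == "paper-10:1") {
    assert_that(binary, "the 10:1 scheme applies to the binary task")
    c("0" = 1, "1" = 10)
  } else {
    w <- 1 / as.numeric(counts)
    w <- w / min(w)
    stats::setNames(w, names(counts))
  }
}

#' Oversample minority classes
#'
#' Duplicates minority-class cubes by seeded sampling with replacement
#' until every class matches the majority count. Apply to training folds
#' only; [cross_validate()] enforces this.
#'
#' @param set A `cube_set`.
#' @param seed Integer seed.
#' @param binary Balance the binary-collapsed classes (default `FALSE`).
#' @return A `cube_set` with duplicated anchor rows.
#' @export
oversample <- function(set, seed = 1L, binary = FALSE) {
  labels <- cube_labels(set, binary = binary)
  counts <- table(labels)
  assert_that(length(counts) >= 2L, "oversampling needs >= 2 classes")
  target <- max(counts)
  extra <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(labels == cl)
      need <- target - length(rows)
      if (need > 0) sample(rows, need, replace = TRUE) else integer()
    }))
  })
  set$anchors <- rbind(set$anchors, set$anchors[extra, , drop = FALSE])
  rownames(set$anchors) <- NULL
  set
}

#' Subset a cube set by cube index
#' @param set A `cube_set`.
#' @param idx Cube indices to keep.
#' @return A `cube_set`.
#' @export
cube_subset <- function(set, idx) {
  set$anchors <- set$anchors[idx, , drop = FALSE]
  rownames(set$anchors) <- NULL
  set
}
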