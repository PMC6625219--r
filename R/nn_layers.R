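# Minimal neural-network layer library: dense, 3x3 same-padding conv,
# 2x2 max-pool, flatten, simple RNN and LSTM, with explicit forward and
# backward passes. Arrays are batch-first: dense activations are
# [n, features], images are [n, H, W, C], sequences are [n, T, D].
# Gradient correctness is pinned by finite-difference tests.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# ---- dense ---------------------------------------------------------------

dense_layer <- function(n_in, n_out, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  sd <- if (activation == "relu") sqrt(2 / n_in) else sqrt(1 / n_in)
  list(kind = "dense", n_in = n_in, n_out = n_out, activation = activation,
       params = list(
         W = matrix(stats::rnorm(n_in * n_out, 0, sd), n_in, n_out),
         b = numeric(n_out)))
}

dense_forward <- function(layer, x) {
  z <- x %*% layer$params$W
  z <- sweep(z, 2, layer$params$b, `+`)
  out <- if (layer$activation == "relu") relu(z) else z
  list(out = out, cache = list(x = x, z = z))
}

dense_backward <- function(layer, cache, dout) {
  if (layer$activation == "relu") dout <- dout * (cache$z > 0)
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = t(cache$x) %*% dout, b = colSums(dout)))
}

# ---- flatten -------------------------------------------------------------

flatten_layer <- function(in_dim) {
  list(kind = "flatten", in_dim = in_dim, params = list())
}

flatten_forward <- function(layer, x) {
  d <- dim(x)
  list(out = matrix(x, nrow = d[1]), cache = list(dim = d))
}

flatten_backward <- function(layer, cache, dout) {
  list(dx = array(dout, cache$dim), grads = list())
}

# ---- conv 3x3, same padding ---------------------------------------------

conv_layer <- function(in_channels, filters) {
  fan_in <- 9 * in_channels
  list(kind = "conv", in_channels = in_channels, filters = filters,
       params = list(
         W = array(stats::rnorm(9 * in_channels * filters, 0,
                                sqrt(2 / fan_in)),
                   c(3L, 3L, in_channels, filters)),
         b = numeric(filters)))
}

pad_hw <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  xp[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  xp
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  f <- layer$filters
  xp <- pad_hw(x)
  zmat <- matrix(rep(layer$params$b, each = n * h * w), n * h * w, f)
  for (dh in 0:2) for (dw in 0:2) {
    slice <- matrix(xp[, (1 + dh):(h + dh), (1 + dw):(w + dw), ,
                       drop = FALSE], ncol = cc)
    zmat <- zmat + slice %*% layer$params$W[dh + 1L, dw + 1L, , ]
  }
  z <- array(zmat, c(n, h, w, f))
  list(out = relu(z), cache = list(xp = xp, z = z, in_dim = d))
}

conv_backward <- function(layer, cache, dout) {
  d <- cache$in_dim
  n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  f <- layer$filters
  dz <- dout * (cache$z > 0)
  dzmat <- matrix(dz, ncol = f)
  dW <- array(0, dim(layer$params$W))
  dxp <- array(0, dim(cache$xp))
  for (dh in 0:2) for (dw in 0:2) {
    slice <- matrix(cache$xp[, (1 + dh):(h + dh), (1 + dw):(w + dw), ,
                             drop = FALSE], ncol = cc)
    dW[dh + 1L, dw + 1L, , ] <- t(slice) %*% dzmat
    dslice <- dzmat %*% t(layer$params$W[dh + 1L, dw + 1L, , ])
    dxp[, (1 + dh):(h + dh), (1 + dw):(w + dw), ] <-
      dxp[, (1 + dh):(h + dh), (1 + dw):(w + dw), ] +
      array(dslice, c(n, h, w, cc))
  }
  list(dx = dxp[, 2:(h + 1L), 2:(w + 1L), , drop = FALSE],
       grads = list(W = dW, b = colSums(dzmat)))
}

# ---- max-pool 2x2, stride 2 ----------------------------------------------

maxpool_layer <- function() list(kind = "maxpool", params = list())

maxpool_forward <- function(layer, x) {
  d <- dim(x)
  assert_that(d[2] %% 2L == 0L && d[3] %% 2L == 0L,
              "max-pool needs even spatial dimensions")
  io <- seq.int(1L, d[2], 2L); ie <- io + 1L
  jo <- seq.int(1L, d[3], 2L); je <- jo + 1L
  cand <- list(x[, io, jo, , drop = FALSE], x[, ie, jo, , drop = FALSE],
               x[, io, je, , drop = FALSE], x[, ie, je, , drop = FALSE])
  out <- cand[[1]]
  which_max <- array(1L, dim(out))
  for (k in 2:4) {
    upd <- cand[[k]] > out
    out[upd] <- cand[[k]][upd]
    which_max[upd] <- k
  }
  list(out = out, cache = list(which_max = which_max, in_dim = d))
}

maxpool_backward <- function(layer, cache, dout) {
  d <- cache$in_dim
  dx <- array(0, d)
  io <- seq.int(1L, d[2], 2L); ie <- io + 1L
  jo <- seq.int(1L, d[3], 2L); je <- jo + 1L
  idx <- list(list(io, jo), list(ie, jo), list(io, je), list(ie, je))
  for (k in 1:4) {
    g <- dout
    g[cache$which_max != k] <- 0
    dx[, idx[[k]][[1]], idx[[k]][[2]], ] <-
      dx[, idx[[k]][[1]], idx[[k]][[2]], ] + g
  }
  list(dx = dx, grads = list())
}

# ---- simple recurrent layer (tanh), returns last hidden state -----------

rnn_layer <- function(n_in, n_hidden) {
  s_in <- sqrt(1 / n_in); s_h <- sqrt(1 / n_hidden)
  list(kind = "rnn", n_in = n_in, n_hidden = n_hidden,
       params = list(
         Wx = matrix(stats::rnorm(n_in * n_hidden, 0, s_in), n_in, n_hidden),
         Wh = matrix(stats::rnorm(n_hidden^2, 0, s_h), n_hidden, n_hidden),
         b = numeric(n_hidden)))
}

rnn_forward <- function(layer, x) {
  d <- dim(x)  # n x T x D
  n <- d[1]; tt <- d[2]
  hdim <- layer$n_hidden
  hs <- array(0, c(n, hdim, tt + 1L))
  for (t in seq_len(tt)) {
    xt <- matrix(x[, t, ], nrow = n)
    a <- xt %*% layer$params$Wx + hs[, , t] %*% layer$params$Wh
    hs[, , t + 1L] <- tanh(sweep(a, 2, layer$params$b, `+`))
  }
  list(out = matrix(hs[, , tt + 1L], nrow = n),
       cache = list(x = x, hs = hs))
}

rnn_backward <- function(layer, cache, dout) {
  x <- cache$x; hs <- cache$hs
  d <- dim(x); n <- d[1]; tt <- d[2]
  dWx <- array(0, dim(layer$params$Wx))
  dWh <- array(0, dim(layer$params$Wh))
  db <- numeric(layer$n_hidden)
  dx <- array(0, d)
  dh <- if (is.null(dim(dout))) matrix(dout, nrow = n) else dout
  for (t in rev(seq_len(tt))) {
    da <- dh * (1 - hs[, , t + 1L]^2)
    xt <- matrix(x[, t, ], nrow = n)
    dWx <- dWx + t(xt) %*% da
    dWh <- dWh + t(matrix(hs[, , t], nrow = n)) %*% da
    db <- db + colSums(da)
    dx[, t, ] <- da %*% t(layer$params$Wx)
    dh <- da %*% t(layer$params$Wh)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- LSTM, returns last hidden state ------------------------------------
# Gate order in the stacked weight matrices: input, forget, cell, output.

lstm_layer <- function(n_in, n_hidden) {
  s_in <- sqrt(1 / n_in); s_h <- sqrt(1 / n_hidden)
  b <- numeric(4L * n_hidden)
  b[(n_hidden + 1L):(2L * n_hidden)] <- 1  # forget-gate bias at 1
  list(kind = "lstm", n_in = n_in, n_hidden = n_hidden,
       params = list(
         Wx = matrix(stats::rnorm(n_in * 4 * n_hidden, 0, s_in),
                     n_in, 4L * n_hidden),
         Wh = matrix(stats::rnorm(n_hidden * 4 * n_hidden, 0, s_h),
                     n_hidden, 4L * n_hidden),
         b = b))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_forward <- function(layer, x) {
  d <- dim(x); n <- d[1]; tt <- d[2]
  hdim <- layer$n_hidden
  hs <- array(0, c(n, hdim, tt + 1L))
  cs <- array(0, c(n, hdim, tt + 1L))
  gates <- array(0, c(n, 4L * hdim, tt))
  for (t in seq_len(tt)) {
    xt <- matrix(x[, t, ], nrow = n)
    a <- sweep(xt %*% layer$params$Wx +
                 matrix(hs[, , t], nrow = n) %*% layer$params$Wh,
               2, layer$params$b, `+`)
    i <- sigmoid(a[, 1:hdim, drop = FALSE])
    f <- sigmoid(a[, (hdim + 1):(2 * hdim), drop = FALSE])
    g <- tanh(a[, (2 * hdim + 1):(3 * hdim), drop = FALSE])
    o <- sigmoid(a[, (3 * hdim + 1):(4 * hdim), drop = FALSE])
    cs[, , t + 1L] <- f * matrix(cs[, , t], nrow = n) + i * g
    hs[, , t + 1L] <- o * tanh(matrix(cs[, , t + 1L], nrow = n))
    gates[, , t] <- cbind(i, f, g, o)
  }
  list(out = matrix(hs[, , tt + 1L], nrow = n),
       cache = list(x = x, hs = hs, cs = cs, gates = gates))
}

lstm_backward <- function(layer, cache, dout) {
  x <- cache$x; hs <- cache$hs; cs <- cache$cs; gates <- cache$gates
  d <- dim(x); n <- d[1]; tt <- d[2]
  hdim <- layer$n_hidden
  dWx <- array(0, dim(layer$params$Wx))
  dWh <- array(0, dim(layer$params$Wh))
  db <- numeric(4L * hdim)
  dx <- array(0, d)
  dh <- if (is.null(dim(dout))) matrix(dout, nrow = n) else dout
  dc <- matrix(0, n, hdim)
  for (t in rev(seq_len(tt))) {
    i <- matrix(gates[, 1:hdim, t], nrow = n)
    f <- matrix(gates[, (hdim + 1):(2 * hdim), t], nrow = n)
    g <- matrix(gates[, (2 * hdim + 1):(3 * hdim), t], nrow = n)
    o <- matrix(gates[, (3 * hdim + 1):(4 * hdim), t], nrow = n)
    ct <- matrix(cs[, , t + 1L], nrow = n)
    tc <- tanh(ct)
    do_ <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g
    dg <- dc * i
    df <- dc * matrix(cs[, , t], nrow = n)
    da <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    xt <- matrix(x[, t, ], nrow = n)
    dWx <- dWx + t(xt) %*% da
    dWh <- dWh + t(matrix(hs[, , t], nrow = n)) %*% da
    db <- db + colSums(da)
    dx[, t, ] <- da %*% t(layer$params$Wx)
    dh <- da %*% t(layer$params$Wh)
    dc <- dc * f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- dispatch ------------------------------------------------------------

layer_forward <- function(layer, x) {
  switch(layer$kind,
         dense = dense_forward(layer, x),
         flatten = flatten_forward(layer, x),
         conv = conv_forward(layer, x),
         maxpool = maxpool_forward(layer, x),
         rnn = rnn_forward(layer, x),
         lstm = lstm_forward(layer, x),
         stop_config(sprintf("unknown layer kind '%s'", layer$kind)))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$kind,
         dense = dense_backward(layer, cache, dout),
         flatten = flatten_backward(layer, cache, dout),
         conv = conv_backward(layer, cache, dout),
         maxpool = maxpool_backward(layer, cache, dout),
         rnn = rnn_backward(layer, cache, dout),
         lstm = lstm_backward(layer, cache, dout),
         stop_config(sprintf("unknown layer kind '%s'", layer$kind)))
}

# Softmax cross-entropy with per-sample weights. y is a 1-based class
# index; weights normalize to sum 1 so the loss scale is batch-invariant.
softmax_xent <- function(scores, y, w) {
  n <- nrow(scores)
  z <- scores - apply(scores, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  wn <- w / sum(w)
  loss <- -sum(wn * log(pmax(p[cbind(seq_len(n), y)], 1e-300)))
  dscores <- p
  dscores[cbind(seq_len(n), y)] <- dscores[cbind(seq_len(n), y)] - 1
  dscores <- dscores * wn
  list(loss = loss, prob = p, dscores = dscores)
}
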