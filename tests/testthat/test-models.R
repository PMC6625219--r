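test_that("family depth audit: weighted layers are 3/5/6/7 and 2/2", {
  expected <- c("ANN" = 3L, "CNN-5" = 5L, "CNN-6" = 6L, "CNN-7" = 7L,
                "RNN" = 2L, "LSTM" = 2L)
  for (fam in names(expected)) {
    m <- build_network(network_spec(fam, 2, c(40L, 40L, 2L)), seed = 1)
    expect_equal(n_weighted_layers(m), unname(expected[fam]), label = fam)
    out_layer <- m$layers[[length(m$layers)]]
    expect_equal(out_layer$n_out, 2L, label = fam)
  }
  # recurrent families see the cube as a 40-step sequence of 80 features
  r <- build_network(network_spec("RNN", 2, c(40L, 40L, 2L)), seed = 1)
  expect_equal(r$layers[[1]]$n_in, 80L)
  expect_error(network_spec("VGG"), "unknown network family")
})

test_that("initialization is seed-deterministic", {
  a <- build_network(network_spec("CNN-5", 2, c(8L, 8L, 2L)), seed = 9)
  b <- build_network(network_spec("CNN-5", 2, c(8L, 8L, 2L)), seed = 9)
  expect_identical(a$layers, b$layers)
  c <- build_network(network_spec("CNN-5", 2, c(8L, 8L, 2L)), seed = 10)
  expect_false(identical(a$layers, c$layers))
})

test_that("analytic gradients match finite differences in every family", {
  shape <- c(4L, 4L, 2L)
  withr::with_seed(9, {
    n <- 4
    x <- array(rnorm(n * prod(shape)), c(n, shape))
    y <- sample(1:2, n, replace = TRUE)
    w <- runif(n, 0.5, 2)
  })
  for (fam in c("ANN", "CNN-5", "CNN-7", "RNN", "LSTM")) {
    m <- build_network(network_spec(fam, 2, shape, hidden = 0.1), seed = 2)
    xb <- nirspain:::shape_input(m, x)
    lossfn <- function(layers) {
      fw <- nirspain:::net_forward(list(spec = m$spec, layers = layers),
                                   xb, keep_cache = TRUE)
      nirspain:::softmax_xent(fw$scores, y, w)
    }
    fw <- nirspain:::net_forward(m, xb, keep_cache = TRUE)
    sm <- nirspain:::softmax_xent(fw$scores, y, w)
    grads <- nirspain:::net_backward(m, fw$caches, sm$dscores)
    worst <- 0
    withr::with_seed(5, {
      for (i in seq_along(m$layers)) {
        for (nm in names(m$layers[[i]]$params)) {
          p <- m$layers[[i]]$params[[nm]]
          for (j in sample(length(p), min(4, length(p)))) {
            eps <- 1e-6
            lp <- m$layers; lp[[i]]$params[[nm]][j] <- p[j] + eps
            lm <- m$layers; lm[[i]]$params[[nm]][j] <- p[j] - eps
            num <- (lossfn(lp)$loss - lossfn(lm)$loss) / (2 * eps)
            ana <- grads[[i]][[nm]][j]
            worst <- max(worst, abs(num - ana) /
                           max(1e-8, abs(num) + abs(ana)))
          }
        }
      }
    })
    expect_lt(worst, 1e-5, label = paste(fam, "gradient"))
  }
})

test_that("training separates a linearly separable toy", {
  toy <- toy_blobs(n = 160, sep = 1.5)
  m <- build_network(network_spec("ANN", 2, c(8L, 8L, 2L), hidden = 0.25),
                     seed = 3)
  m <- train(m, toy, train_config(epochs = 15, batch_size = 32, seed = 4))
  pred <- predict(m, toy)
  expect_gte(mean(pred$codes == toy$labels), 0.99)
  # smoothed loss decreases over training
  expect_lt(mean(tail(m$log, 3)), mean(head(m$log, 3)))
})

test_that("training and inference are deterministic given the seed", {
  toy <- toy_blobs(n = 60, sep = 1)
  spec <- network_spec("LSTM", 2, c(8L, 8L, 2L), hidden = 0.2)
  m1 <- train(build_network(spec, 7), toy,
              train_config(epochs = 3, batch_size = 16, seed = 8))
  m2 <- train(build_network(spec, 7), toy,
              train_config(epochs = 3, batch_size = 16, seed = 8))
  expect_equal(m1$log, m2$log, tolerance = 1e-12)
  p1 <- predict(m1, toy)
  p2 <- predict(m2, toy)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
  # duplicate cube -> identical probabilities
  dup <- list(x = toy$x[c(1, 1), , , , drop = FALSE])
  pd <- predict(m1, dup)
  expect_identical(pd$prob[1, ], pd$prob[2, ])
})

test_that("probabilities are normalized and inputs are validated", {
  toy <- toy_blobs(n = 40, sep = 0.5)
  m <- train(build_network(network_spec("ANN", 2, c(8L, 8L, 2L),
                                        hidden = 0.2), 1),
             toy, train_config(epochs = 1, seed = 1))
  p <- predict(m, toy)
  expect_equal(rowSums(p$prob), rep(1, 40), tolerance = 1e-6)
  expect_true(all(p$codes %in% 0:1))
  wrong <- list(x = array(0, c(3, 5, 5, 2)), labels = c(0L, 1L, 0L))
  expect_error(predict(m, wrong), "shape")
  expect_error(train(m, wrong, train_config(epochs = 1)), "shape")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(
    train(build_network(network_spec("ANN", 2, c(8L, 8L, 2L)), 1), toy,
          train_config(epochs = 1, weights = c("0" = 1))),
    "weight map")
})

test_that("class weighting shifts the decision toward the minority", {
  # overlapping blobs at 12:1 imbalance; weighting must raise minority
  # recall in most paired runs
  withr::with_seed(40, {
    n <- 260
    y <- rep(c(0L, 1L), c(240, 20))
    x <- array(rnorm(n * 4 * 4 * 2, mean = rep(y * 0.8, 32)),
               c(n, 4L, 4L, 2L))
  })
  data <- list(x = x, labels = y)
  wins <- 0L
  for (s in 1:3) {
    spec <- network_spec("ANN", 2, c(4L, 4L, 2L), hidden = 0.2)
    m0 <- build_network(spec, seed = 50 + s)
    mu <- train(m0, data, train_config(epochs = 6, seed = 60 + s))
    mw <- train(m0, data, train_config(epochs = 6, seed = 60 + s,
                                       weights = c("0" = 1, "1" = 10)))
    sens <- function(m) {
      cm <- confusion(y, predict(m, data)$codes)
      metrics(cm)$sensitivity
    }
    if (sens(mw) > sens(mu)) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("model artifacts round-trip through JSON", {
  toy <- toy_blobs(n = 30, sep = 1)
  m <- train(build_network(network_spec("CNN-5", 2, c(8L, 8L, 2L),
                                        hidden = 0.15), 2),
             toy, train_config(epochs = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict(back, toy)$prob, predict(m, toy)$prob,
               tolerance = 0)
  expect_equal(n_weighted_layers(back), 5L)
})
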