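# The six classifier families compared for pain decoding. The published
# comparison states only the number of weighted layers per family (3 for
# the ANN, 5/6/7 for the CNNs); the widths, kernels and optimizer used
# here are this package's reconstruction (see the methods vignette) and
# are configurable through network_spec(). The layer-count convention:
# layers with trainable weights (dense, conv, recurrent) count toward the
# family depth; pooling and flatten do not.

NN_FAMILIES <- c("ANN", "CNN-5", "CNN-6", "CNN-7", "RNN", "LSTM")

#' Classifier architecture specification
#'
#' @param family One of `"ANN"` (3 weighted layers), `"CNN-5"`, `"CNN-6"`,
#'   `"CNN-7"` (5/6/7 weighted layers), `"RNN"`, `"LSTM"` (one recurrent
#'   layer plus the output layer).
#' @param n_classes 2 (pain/no-pain) or 3 (no-pain/right/left).
#' @param input_shape Cube shape `c(T, channels, 2)`; `T` is 40 for type-I
#'   cubes and 80 for type-II.
#' @param hidden Width scaling of the reconstruction's dense/recurrent
#'   layers (default 1; e.g. 0.5 halves every width, for quick tests).
#' @return A `network_spec`.
#' @export
network_spec <- function(family = "ANN", n_classes = 2L,
                         input_shape = c(40L, 40L, 2L), hidden = 1) {
  if (!family %in% NN_FAMILIES) {
    stop_config(sprintf("unknown network family '%s' (known: %s)",
                        family, paste(NN_FAMILIES, collapse = ", ")))
  }
  assert_that(n_classes %in% 2:3, "n_classes must be 2 or 3")
  assert_that(length(input_shape) == 3L && input_shape[3] == 2L,
              "input_shape must be c(T, channels, 2)")
  structure(list(family = family, n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape), hidden = hidden),
            class = "network_spec")
}

scale_width <- function(w, s) max(4L, as.integer(round(w * s)))

#' Build an untrained network
#'
#' Instantiates the layer plan for a [network_spec()] with seeded random
#' initialization (He/Glorot scaling).
#'
#' @param spec A `network_spec`.
#' @param seed Integer seed for the initialization.
#' @return An `nn_model` with untrained parameters.
#' @export
build_network <- function(spec, seed = 1L) {
  d <- spec$input_shape
  k <- spec$n_classes
  s <- spec$hidden
  flat_in <- prod(d)
  seq_d <- d[2] * d[3]
  with_seed(seed, {
    layers <- switch(
      spec$family,
      "ANN" = list(
        flatten_layer(d),
        dense_layer(flat_in, scale_width(128L, s)),
        dense_layer(scale_width(128L, s), scale_width(64L, s)),
        dense_layer(scale_width(64L, s), k, activation = "linear")),
      "CNN-5" = {
        fm <- (d[1] / 2) * (d[2] / 2) * 32L
        list(conv_layer(2L, 16L), conv_layer(16L, 32L), maxpool_layer(),
             flatten_layer(c(d[1] / 2, d[2] / 2, 32L)),
             dense_layer(fm, scale_width(64L, s)),
             dense_layer(scale_width(64L, s), scale_width(32L, s)),
             dense_layer(scale_width(32L, s), k, activation = "linear"))
      },
      "CNN-6" = {
        fm <- (d[1] / 2) * (d[2] / 2) * 64L
        list(conv_layer(2L, 16L), conv_layer(16L, 32L), maxpool_layer(),
             conv_layer(32L, 64L),
             flatten_layer(c(d[1] / 2, d[2] / 2, 64L)),
             dense_layer(fm, scale_width(64L, s)),
             dense_layer(scale_width(64L, s), scale_width(32L, s)),
             dense_layer(scale_width(32L, s), k, activation = "linear"))
      },
      "CNN-7" = {
        fm <- (d[1] / 2) * (d[2] / 2) * 64L
        list(conv_layer(2L, 16L), conv_layer(16L, 32L), maxpool_layer(),
             conv_layer(32L, 64L),
             flatten_layer(c(d[1] / 2, d[2] / 2, 64L)),
             dense_layer(fm, scale_width(128L, s)),
             dense_layer(scale_width(128L, s), scale_width(64L, s)),
             dense_layer(scale_width(64L, s), scale_width(32L, s)),
             dense_layer(scale_width(32L, s), k, activation = "linear"))
      },
      "RNN" = list(
        rnn_layer(seq_d, scale_width(64L, s)),
        dense_layer(scale_width(64L, s), k, activation = "linear")),
      "LSTM" = list(
        lstm_layer(seq_d, scale_width(64L, s)),
        dense_layer(scale_width(64L, s), k, activation = "linear"))
    )
    structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                   classes = if (k == 2L) 0:1 else 0:2,
                   trained = FALSE, log = NULL, provenance = NULL),
              class = "nn_model")
  })
}

#' Count layers with trainable weights
#'
#' The depth audit for the family naming convention: dense, convolutional
#' and recurrent layers count; pooling and flatten do not.
#'
#' @param model An `nn_model`.
#' @return Integer count.
#' @export
n_weighted_layers <- function(model) {
  sum(vapply(model$layers, function(l)
    l$kind %in% c("dense", "conv", "rnn", "lstm"), TRUE))
}

#' Total trainable parameter count
#' @param model An `nn_model`.
#' @return Integer.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$params, length, 0L)), 0L))
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model> %s, %d classes, input %s: %d weighted layers, %d parameters%s\n",
              x$spec$family, x$spec$n_classes,
              paste(x$spec$input_shape, collapse = "x"),
              n_weighted_layers(x), n_parameters(x),
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# Prepare a batch tensor in the shape the first layer expects.
shape_input <- function(model, x4d) {
  d <- dim(x4d)
  if (model$layers[[1]]$kind %in% c("rnn", "lstm")) {
    array(x4d, c(d[1], d[2], d[3] * d[4]))  # n x T x (channels*chrom)
  } else {
    x4d
  }
}

net_forward <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], x)
    x <- fw$out
    if (keep_cache) caches[[i]] <- fw$cache
  }
  list(scores = x, caches = caches)
}

net_backward <- function(model, caches, dscores) {
  grads <- vector("list", length(model$layers))
  dout <- dscores
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], caches[[i]], dout)
    grads[[i]] <- bw$grads
    dout <- bw$dx
  }
  grads
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param epochs Number of passes over the training cubes (default 20,
#'   must be >= 1).
#' @param weights Named class-weight map (names = label codes), e.g.
#'   `class_weights(set)`; `NULL` trains unweighted.
#' @param seed Seed controlling shuffling (and recorded in provenance).
#' @param grad_clip Global gradient-norm clip (default 5; stabilizes
#'   training on heavy-tailed normalized features).
#' @return A `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 64L, epochs = 20L,
                         weights = NULL, seed = 1L, grad_clip = 5) {
  assert_that(epochs >= 1, "epochs must be >= 1")
  if (!is.null(weights)) {
    assert_that(all(weights > 0), "class weights must be positive")
  }
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), weights = weights,
                 seed = as.integer(seed), grad_clip = grad_clip),
            class = "train_config")
}

adam_init <- function(layers) {
  lapply(layers, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim(p) %||% length(p)),
         v = array(0, dim(p) %||% length(p)))
  }))
}

adam_step <- function(layers, grads, state, lr, t, clip,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gnorm <- sqrt(sum(vapply(grads, function(g)
    sum(vapply(g, function(x) sum(x^2), 0)), 0)))
  scale <- if (is.finite(clip) && gnorm > clip) clip / gnorm else 1
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]] * scale
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Resolve training data: a cube_set, or list(x = 4-d array, labels =).
resolve_data <- function(model, data) {
  binary <- model$spec$n_classes == 2L
  if (inherits(data, "cube_set")) {
    list(fetch = function(idx) cube_array(data, idx),
         labels = cube_labels(data, binary = binary),
         n = n_cubes(data),
         id = sprintf("cube_set(%d cubes, type %d)", n_cubes(data),
                      data$cube_type))
  } else {
    labels <- as.integer(data$labels)
    if (binary) labels <- collapse_binary(labels)
    list(fetch = function(idx) data$x[idx, , , , drop = FALSE],
         labels = labels, n = length(labels), id = "array")
  }
}

#' Train a classifier on feature cubes
#'
#' Mini-batch Adam on class-weighted softmax cross-entropy. For a 2-class
#' model, labels are collapsed to pain/no-pain automatically. Training is
#' deterministic given the configuration seed (single-threaded numeric
#' policy assumed).
#'
#' @param model An untrained (or trained) `nn_model` from
#'   [build_network()].
#' @param data A `cube_set`, or `list(x = n x T x ch x 2 array,
#'   labels = codes)`.
#' @param config A [train_config()].
#' @return The trained `nn_model`, with `$log` (per-epoch mean weighted
#'   loss) and `$provenance`.
#' @export
train <- function(model, data, config = train_config()) {
  src <- resolve_data(model, data)
  assert_that(src$n > 0, "no training cubes")
  y_codes <- src$labels
  cls <- model$classes
  assert_that(all(y_codes %in% cls), "labels outside the model's classes")
  y <- match(y_codes, cls)
  w_map <- config$weights
  if (is.null(w_map)) {
    w <- rep(1, src$n)
  } else {
    present <- unique(y_codes)
    missing_w <- setdiff(as.character(present), names(w_map))
    assert_that(length(missing_w) == 0L,
                sprintf("class(es) %s absent from the weight map",
                        paste(missing_w, collapse = ", ")))
    w <- as.numeric(w_map[as.character(y_codes)])
  }
  dims_ok <- identical(as.integer(dim(src$fetch(1L))[2:4]),
                       model$spec$input_shape)
  assert_that(dims_ok, "cube shape does not match the model's input shape")

  layers <- model$layers
  state <- adam_init(layers)
  log <- numeric(config$epochs)
  step <- 0L
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(src$n)
      losses <- c()
      for (start in seq.int(1L, src$n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, src$n)]
        xb <- shape_input(model, src$fetch(idx))
        fw_model <- list(spec = model$spec, layers = layers)
        fw <- net_forward(fw_model, xb, keep_cache = TRUE)
        sm <- softmax_xent(fw$scores, y[idx], w[idx])
        grads <- net_backward(fw_model, fw$caches, sm$dscores)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, config$lr, step,
                         config$grad_clip)
        layers <- upd$layers
        state <- upd$state
        losses <- c(losses, sm$loss)
      }
      log[ep] <- mean(losses)
    }
  })
  model$layers <- layers
  model$trained <- TRUE
  model$log <- log
  model$provenance <- list(data = src$id, config = unclass(config),
                           seed = config$seed, timestampless = TRUE)
  model
}

#' Predict class probabilities and state codes
#'
#' @param object A trained `nn_model`.
#' @param data A `cube_set` or `list(x = array)` (labels ignored).
#' @param batch_size Inference batch size (default 256).
#' @param ... Unused.
#' @return List with `prob` (matrix, one column per class code, rows sum
#'   to 1) and `codes` (argmax state codes).
#' @export
predict.nn_model <- function(object, data, batch_size = 256L, ...) {
  src <- if (inherits(data, "cube_set")) {
    list(fetch = function(idx) cube_array(data, idx), n = n_cubes(data))
  } else if (is.list(data) && !is.null(data$x)) {
    list(fetch = function(idx) data$x[idx, , , , drop = FALSE],
         n = dim(data$x)[1])
  } else {
    stop_validation("data must be a cube_set or list(x = 4-d array)")
  }
  d1 <- dim(src$fetch(1L))[2:4]
  assert_that(identical(as.integer(d1), object$spec$input_shape),
              "cube shape does not match the model's input shape")
  probs <- matrix(NA_real_, src$n, object$spec$n_classes)
  for (start in seq.int(1L, src$n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, src$n)
    xb <- shape_input(object, src$fetch(idx))
    scores <- net_forward(object, xb)$scores
    z <- scores - apply(scores, 1, max)
    ez <- exp(z)
    probs[idx, ] <- ez / rowSums(ez)
  }
  colnames(probs) <- as.character(object$classes)
  list(prob = probs, codes = object$classes[max.col(probs, "first")])
}

# ---- portable serialization ---------------------------------------------

#' Save a model as a portable JSON artifact
#' @param model An `nn_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  ser_layers <- lapply(model$layers, function(l) {
    l$params <- lapply(l$params, function(p)
      list(dim = dim(p) %||% length(p), data = num_to_chr(as.vector(p))))
    l
  })
  obj <- list(container = "nirspain-model", version = 1L,
              spec = unclass(model$spec), classes = model$classes,
              seed = model$seed, trained = model$trained,
              log = num_to_chr(model$log %||% numeric()),
              layers = ser_layers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Artifact path.
#' @return An `nn_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$container, "nirspain-model")) {
    stop_parse("not a nirspain model artifact (field 'container')")
  }
  layers <- lapply(obj$layers, function(l) {
    l$params <- lapply(l$params, function(p) {
      v <- chr_to_num(p$data)
      if (length(p$dim) > 1L) array(v, as.integer(p$dim)) else v
    })
    l
  })
  spec <- do.call(network_spec, obj$spec[c("family", "n_classes",
                                           "input_shape", "hidden")])
  structure(list(spec = spec, layers = layers, seed = obj$seed,
                 classes = as.integer(obj$classes),
                 trained = obj$trained,
                 log = chr_to_num(obj$log), provenance = NULL),
            class = "nn_model")
}
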