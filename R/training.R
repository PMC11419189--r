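#' Training configuration
#'
#' Fixed hyperparameters of the study: Adam with learning rate 0.001 and betas
#' 0.9 / 0.999, minibatch size 128, categorical cross-entropy, and a 90/10
#' train/validation split of the training data.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Minibatch size. Default 128.
#' @param learning_rate,beta1,beta2,epsilon Adam parameters. Defaults 0.001,
#'   0.9, 0.999, 1e-8.
#' @param val_fraction Fraction of the training data held out for validation,
#'   in (0, 1). Default 0.1.
#' @param seed Integer run seed controlling initialization, the validation
#'   split, and epoch shuffling.
#' @param shuffle Reshuffle the training split every epoch. Default `TRUE`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, batch_size = 128L, learning_rate = 0.001,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         val_fraction = 0.1, seed = 1L, shuffle = TRUE) {
  structure(list(epochs = assert_count(epochs, "epochs"),
                 batch_size = assert_count(batch_size, "batch_size"),
                 learning_rate = as.numeric(learning_rate),
                 beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
                 epsilon = as.numeric(epsilon),
                 val_fraction = assert_fraction(val_fraction, "val_fraction"),
                 seed = assert_count(seed, "seed", min = 0L),
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

#' Epoch budgets used in the study
#'
#' Preset epoch counts per dataset family: 15 for MNIST, 20 for FMNIST and
#' KMNIST, 50 for EMNIST, CIFAR10 and the sequential-learning task.
#'
#' @param dataset One of `"mnist"`, `"fmnist"`, `"kmnist"`, `"emnist"`,
#'   `"cifar10"`, `"sequential"`, `"synthetic"`.
#' @return Integer epoch count.
#' @export
epoch_preset <- function(dataset) {
  presets <- c(mnist = 15L, fmnist = 20L, kmnist = 20L, emnist = 50L,
               cifar10 = 50L, sequential = 50L, synthetic = 15L)
  key <- match.arg(tolower(dataset), names(presets))
  presets[[key]]
}

one_hot <- function(y, n_classes) {
  if (any(y < 0L | y >= n_classes | y != as.integer(y))) {
    stop("labels must be integers in [0, n_classes)", call. = FALSE)
  }
  m <- matrix(0, nrow = length(y), ncol = n_classes)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# One forward/backward pass on a batch; returns masked gradients plus batch
# loss and accuracy. Gradient masking zeroes every gradient of a non-existent
# connection before the optimizer sees it.
backprop <- function(params, spec, X, Y) {
  n <- nrow(X)
  slope <- spec$leaky_slope
  z1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  a1 <- leaky_relu(z1, slope)
  z2 <- sweep(a1 %*% params$W2, 2L, params$b2, "+")
  a2 <- leaky_relu(z2, slope)
  z3 <- sweep(a2 %*% params$W3, 2L, params$b3, "+")
  logp <- log_softmax_rows(z3)
  probs <- exp(logp)
  loss <- -sum(Y * logp) / n
  acc <- mean(max.col(probs, ties.method = "first") == max.col(Y))

  dz3 <- (probs - Y) / n
  dW3 <- crossprod(a2, dz3)
  db3 <- colSums(dz3)
  da2 <- tcrossprod(dz3, params$W3)
  dz2 <- da2 * leaky_relu_grad(z2, slope)
  dW2 <- crossprod(a1, dz2) * spec$masks$structure_mask
  db2 <- colSums(dz2)
  da1 <- tcrossprod(dz2, params$W2)
  dz1 <- da1 * leaky_relu_grad(z1, slope)
  dW1 <- crossprod(X, dz1) * spec$masks$input_mask
  db1 <- colSums(dz1)

  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3),
       loss = loss, acc = acc)
}

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (k in names(grads)) {
    state$m[[k]] <- cfg$beta1 * state$m[[k]] + (1 - cfg$beta1) * grads[[k]]
    state$v[[k]] <- cfg$beta2 * state$v[[k]] + (1 - cfg$beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      cfg$learning_rate * (state$m[[k]] / bc1) /
        (sqrt(state$v[[k]] / bc2) + cfg$epsilon)
  }
  list(params = params, state = state)
}

#' Train a (masked) two-hidden-layer classifier
#'
#' Minibatch Adam on categorical cross-entropy with gradient masking: after
#' every gradient computation the hidden-layer weight gradients are multiplied
#' elementwise by the boolean masks, and after every parameter update the
#' weights are re-masked, so the support of each weight matrix never leaves
#' its mask. Fully reproducible for a fixed `config$seed`.
#'
#' @param spec A [model_spec()].
#' @param data List with `X` (matrix, rows are observations, intensities
#'   finite) and `y` (integer class ids in `[0, n_classes)`), or an
#'   `image_dataset`.
#' @param config A [train_config()].
#' @param val Optional explicit validation set (same structure as `data`).
#'   When `NULL`, a stratified `val_fraction` split of `data` is used.
#' @param batch_stream Optional function `(epoch) -> list of integer index
#'   vectors` into the training split, overriding the default shuffled
#'   minibatching. Used for the sequential single-class task; the trainer is
#'   otherwise identical.
#' @param init Optional initial `model_params`; default
#'   `init_params(spec, config$seed)`.
#' @param verbose Log per-epoch metrics to `stderr`. Default `FALSE`.
#' @return List with `params` (trained `model_params`) and `history`
#'   (a `train_history`).
#' @export
train <- function(spec, data, config, val = NULL, batch_stream = NULL,
                  init = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "train_config"))
  data <- as_xy(data)
  assert_finite_matrix(data$X, "X")
  if (any(data$y < 0L | data$y >= spec$n_classes)) {
    stop("labels must be integers in [0, n_classes)", call. = FALSE)
  }
  if (is.null(val)) {
    sp <- train_val_split(data, val_fraction = config$val_fraction,
                          seed = config$seed)
    tr <- sp$train; va <- sp$val
  } else {
    tr <- data; va <- as_xy(val)
  }
  Ytr <- one_hot(tr$y, spec$n_classes)
  n <- nrow(tr$X)

  params <- init %||% init_params(spec, config$seed)
  state <- adam_init(params)

  # All epoch permutations drawn up front from one seeded stream, so the
  # trajectory is a pure function of (spec, data, config).
  orders <- with_seed(config$seed + 1L, {
    lapply(seq_len(config$epochs), function(e) {
      if (config$shuffle) sample.int(n) else seq_len(n)
    })
  })

  hist <- list(train_loss = numeric(config$epochs),
               train_acc = numeric(config$epochs),
               val_loss = numeric(config$epochs),
               val_acc = numeric(config$epochs))

  for (epoch in seq_len(config$epochs)) {
    batches <- if (is.null(batch_stream)) {
      ord <- orders[[epoch]]
      split(ord, ceiling(seq_along(ord) / config$batch_size))
    } else {
      batch_stream(epoch)
    }
    bl <- numeric(length(batches)); ba <- numeric(length(batches))
    bn <- integer(length(batches))
    for (i in seq_along(batches)) {
      idx <- batches[[i]]
      bp <- backprop(params, spec, tr$X[idx, , drop = FALSE],
                     Ytr[idx, , drop = FALSE])
      if (!is.finite(bp$loss)) {
        stop(sprintf("non-finite training loss at epoch %d, batch %d",
                     epoch, i), call. = FALSE)
      }
      up <- adam_step(params, bp$grads, state, config)
      params <- apply_masks(up$params, spec$masks)
      state <- up$state
      bl[i] <- bp$loss; ba[i] <- bp$acc; bn[i] <- length(idx)
    }
    hist$train_loss[epoch] <- stats::weighted.mean(bl, bn)
    hist$train_acc[epoch] <- 100 * stats::weighted.mean(ba, bn)
    ev <- evaluate(params, spec, va)
    hist$val_loss[epoch] <- ev$loss
    hist$val_acc[epoch] <- ev$accuracy
    if (verbose) {
      message(sprintf(
        "epoch %d/%d train_loss=%.4f train_acc=%.2f val_loss=%.4f val_acc=%.2f",
        epoch, config$epochs, hist$train_loss[epoch], hist$train_acc[epoch],
        hist$val_loss[epoch], hist$val_acc[epoch]))
    }
  }
  history <- structure(hist, class = "train_history")
  list(params = params, history = history)
}

as_xy <- function(data) {
  if (inherits(data, "image_dataset")) {
    list(X = data$X, y = data$y)
  } else if (is.list(data) && !is.null(data$X) && !is.null(data$y)) {
    list(X = data$X, y = as.integer(data$y))
  } else {
    stop("`data` must be an image_dataset or a list(X, y)", call. = FALSE)
  }
}

#' Evaluate a model on a labelled set
#'
#' Mean categorical cross-entropy and percent top-1 accuracy; deterministic.
#'
#' @param params A `model_params`.
#' @param spec A [model_spec()].
#' @param data List with `X` and `y` or an `image_dataset`; must be non-empty.
#' @return List with `loss` and `accuracy` (percent, in `[0, 100]`).
#' @export
evaluate <- function(params, spec, data) {
  data <- as_xy(data)
  if (is.null(data$X) || nrow(data$X) == 0L) {
    stop("empty evaluation set", call. = FALSE)
  }
  fw <- forward(params, spec, data$X)
  n <- nrow(data$X)
  loss <- -sum(fw$log_probs[cbind(seq_len(n), data$y + 1L)]) / n
  pred <- max.col(fw$probs, ties.method = "first") - 1L
  list(loss = loss, accuracy = 100 * mean(pred == data$y))
}

#' Epoch of minimum validation loss
#'
#' 1-based index of the first minimum of the per-epoch validation loss; the
#' convergence-speed component of the efficiency factor.
#'
#' @param history A `train_history` (or anything with a `val_loss` vector).
#' @return Positive integer.
#' @export
epochs_to_min_val_loss <- function(history) {
  vl <- history$val_loss
  if (is.null(vl) || length(vl) == 0L) stop("empty history", call. = FALSE)
  which.min(vl)  # first occurrence on ties
}

#' @export
as.data.frame.train_history <- function(x, ...) {
  data.frame(epoch = seq_along(x$train_loss),
             train_loss = x$train_loss, train_acc = x$train_acc,
             val_loss = x$val_loss, val_acc = x$val_acc)
}

#' @export
print.train_history <- function(x, ...) {
  e <- epochs_to_min_val_loss(x)
  cat(sprintf("<train_history> %d epochs; min val_loss %.4f at epoch %d\n",
              length(x$val_loss), x$val_loss[e], e))
  invisible(x)
}

#' Write a training history as CSV
#'
#' Columns `epoch, train_loss, train_acc, val_loss, val_acc`.
#'
#' @param history A `train_history`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
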