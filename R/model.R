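#' Model specification for a two-hidden-layer classifier
#'
#' Couples the wiring (`mask_pair`) with the output dimension and activation.
#' All hidden nodes use the leaky rectifier `f(z) = z` for `z > 0`,
#' `slope * z` otherwise; the output layer is a softmax.
#'
#' @param masks A `mask_pair` (use [dense_masks()] for a vanilla network).
#' @param n_classes Number of output classes.
#' @param leaky_slope Negative-side slope of the hidden activation.
#'   Default 0.1.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(masks, n_classes, leaky_slope = 0.1) {
  stopifnot(inherits(masks, "mask_pair"))
  n_classes <- assert_count(n_classes, "n_classes")
  if (ncol(masks$input_mask) != nrow(masks$structure_mask)) {
    stop("mask shapes disagree: ncol(input_mask) != nrow(structure_mask)",
         call. = FALSE)
  }
  structure(list(masks = masks,
                 n_features = nrow(masks$input_mask),
                 n_hidden1 = ncol(masks$input_mask),
                 n_hidden2 = ncol(masks$structure_mask),
                 n_classes = n_classes,
                 leaky_slope = as.numeric(leaky_slope)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s> %d -> %d -> %d -> %d (%s params)\n",
              x$masks$scheme, x$n_features, x$n_hidden1, x$n_hidden2,
              x$n_classes, format(count_trainable_params(x), big.mark = ",")))
  invisible(x)
}

leaky_relu <- function(z, slope) {
  ifelse(z > 0, z, slope * z)
}

leaky_relu_grad <- function(z, slope) {
  ifelse(z > 0, 1, slope)
}

# Row-wise numerically stable softmax (max subtraction).
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Row-wise log-softmax for stable cross-entropy.
log_softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  z - log(rowSums(exp(z)))
}

#' Initialize model parameters
#'
#' Glorot-uniform weights (`limit = sqrt(6 / (fan_in + fan_out))`), zero
#' biases, followed by mask application so off-mask weights start (and stay)
#' exactly zero.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return An object of class `model_params`: `W1, b1, W2, b2, W3, b3`.
#' @export
init_params <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  params <- with_seed(seed, {
    list(W1 = glorot(spec$n_features, spec$n_hidden1),
         b1 = numeric(spec$n_hidden1),
         W2 = glorot(spec$n_hidden1, spec$n_hidden2),
         b2 = numeric(spec$n_hidden2),
         W3 = glorot(spec$n_hidden2, spec$n_classes),
         b3 = numeric(spec$n_classes))
  })
  class(params) <- "model_params"
  apply_masks(params, spec$masks)
}

#' Apply boolean masks to the weight matrices
#'
#' Elementwise (Hadamard) product of each hidden-layer weight matrix with its
#' boolean mask: `Wk <- Wk * Mk` for layers 1 and 2. The output layer and all
#' biases are untouched. Applied after initialization and after every
#' optimizer update, this keeps off-mask weights exactly zero.
#'
#' @param params A `model_params`.
#' @param masks A `mask_pair`.
#' @return The masked `model_params`.
#' @export
apply_masks <- function(params, masks) {
  stopifnot(inherits(masks, "mask_pair"))
  if (!identical(dim(params$W1), dim(masks$input_mask)) ||
      !identical(dim(params$W2), dim(masks$structure_mask))) {
    stop("parameter and mask shapes disagree", call. = FALSE)
  }
  params$W1 <- params$W1 * masks$input_mask
  params$W2 <- params$W2 * masks$structure_mask
  params
}

#' Forward pass
#'
#' `A1 = f(X W1 + b1)`, `A2 = f(A1 W2 + b2)`,
#' `Y_hat = softmax(A2 W3 + b3)` with the leaky rectifier `f`. Inputs are
#' row-wise observations.
#'
#' @param params A `model_params`.
#' @param spec A [model_spec()].
#' @param X Numeric matrix `(n x n_features)` with finite entries.
#' @return List with `a1`, `a2` (hidden activations), `probs` (softmax rows)
#'   and `log_probs`.
#' @export
forward <- function(params, spec, X) {
  assert_finite_matrix(X, "X")
  if (ncol(X) != spec$n_features) {
    stop("X has the wrong number of feature columns", call. = FALSE)
  }
  z1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
  a1 <- leaky_relu(z1, spec$leaky_slope)
  z2 <- sweep(a1 %*% params$W2, 2L, params$b2, "+")
  a2 <- leaky_relu(z2, spec$leaky_slope)
  z3 <- sweep(a2 %*% params$W3, 2L, params$b3, "+")
  list(a1 = a1, a2 = a2, probs = softmax_rows(z3),
       log_probs = log_softmax_rows(z3))
}

#' Count trainable parameters
#'
#' On-mask weights of the two hidden layers, the full (dense) output layer,
#' and all biases. For a dense mask pair this reduces to the usual dense
#' parameter count.
#'
#' @param spec A [model_spec()].
#' @return Integer-valued count.
#' @examples
#' mp <- dann_masks("R", c(28, 28), n_somata = 10, dendrites_per_soma = 8)
#' count_trainable_params(model_spec(mp, n_classes = 10))  # 1560
#' @export
count_trainable_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  sum(spec$masks$input_mask) + sum(spec$masks$structure_mask) +
    spec$n_hidden2 * spec$n_classes +
    spec$n_hidden1 + spec$n_hidden2 + spec$n_classes
}

#' Save / load a model checkpoint
#'
#' Single-archive serialization of parameters, masks, spec and the seeds used;
#' the round trip is bit-exact.
#'
#' @param params A `model_params`.
#' @param spec A [model_spec()].
#' @param path File path (conventionally `.rds`).
#' @param history Optional training history to store alongside.
#' @param seed Optional run seed to record.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint` a
#'   list with `params`, `spec`, `history`, `seed`.
#' @export
write_checkpoint <- function(params, spec, path, history = NULL, seed = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "model_spec"))
  saveRDS(list(params = params, spec = spec, history = history, seed = seed,
               package_version = as.character(utils::packageVersion("dendrann"))),
          path, compress = "gzip")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || !inherits(x$params, "model_params")) {
    stop("not a model checkpoint", call. = FALSE)
  }
  x
}
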