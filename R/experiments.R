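#' Add Gaussian pixel noise to images
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation `sigma` (on
#' the `[0, 1]` intensity scale) to every pixel, producing datasets of
#' increasing classification difficulty. The transform touches only the data,
#' never model or trainer state.
#'
#' @param data An [image_dataset()], or a bare intensity matrix in `[0, 1]`.
#' @param sigma Noise standard deviation, `>= 0`.
#' @param seed Integer seed; reproducible per seed.
#' @param clip Clip the result back to `[0, 1]` (the valid intensity range).
#'   Default `TRUE`; `FALSE` exposes the raw noisy values, e.g. for checking
#'   the noise moments.
#' @return Same type as the input, with noisy pixels.
#' @export
add_gaussian_noise <- function(data, sigma, seed = 1L, clip = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  is_ds <- inherits(data, "image_dataset")
  X <- if (is_ds) data$X else data
  if (min(X) < 0 || max(X) > 1) {
    stop("images must be scaled to [0, 1]", call. = FALSE)
  }
  if (sigma > 0) {
    X <- X + with_seed(seed, {
      matrix(stats::rnorm(length(X), 0, sigma), nrow(X), ncol(X))
    })
    if (clip) X <- pmin(pmax(X, 0), 1)
  }
  if (is_ds) {
    if (!clip) {
      # out-of-range intensities cannot live in an image_dataset
      return(X)
    }
    data$X <- X
    data
  } else {
    X
  }
}

#' Single-class sequential batch stream
#'
#' Builds the batch order of the sequential-learning task: within an epoch,
#' all minibatches of one class are presented before any batch of the next
#' class, every batch is single-class, each class's final batch may be
#' smaller than `batch_size`, and every image appears exactly once per epoch.
#' The class order is fixed across epochs (ascending class id by default).
#' Feed the result to [train()] via its `batch_stream` argument; the trainer
#' itself is unchanged.
#'
#' @param y Integer label vector of the training split (or an
#'   [image_dataset()]).
#' @param class_order Permutation of the class ids present in `y`. Default
#'   ascending.
#' @param batch_size Minibatch size. Default 128.
#' @return List of integer index vectors (one per batch), each carrying a
#'   `"class"` attribute; suitable as `batch_stream = function(epoch) ...`.
#' @export
sequential_batches <- function(y, class_order = NULL, batch_size = 128L) {
  if (inherits(y, "image_dataset")) y <- y$y
  y <- as.integer(y)
  batch_size <- assert_count(batch_size, "batch_size")
  present <- sort(unique(y))
  class_order <- as.integer(class_order %||% present)
  if (!identical(sort(class_order), present)) {
    stop("`class_order` must be a permutation of the class ids in `y`",
         call. = FALSE)
  }
  batches <- list()
  for (cl in class_order) {
    idx <- which(y == cl)
    if (length(idx) == 0L) stop("empty class in `y`", call. = FALSE)
    parts <- split(idx, ceiling(seq_along(idx) / batch_size))
    for (p in parts) {
      attr(p, "class_id") <- cl
      batches[[length(batches) + 1L]] <- p
    }
  }
  batches
}

#' Size-grid experiment runner
#'
#' Trains every (model family, size, seed) combination on a dataset, records
#' parameter counts, convergence epochs and test metrics, and scores
#' efficiency within the cohort of all trained runs. This is the harness
#' behind parameter-efficiency comparisons of dendritic versus fully
#' connected architectures.
#'
#' @param families `data.frame` with columns `scheme` (one of `"R"`, `"LRF"`,
#'   `"GRF"`, `"F"`, `"sparse"`, `"dense"`), `n_somata` (or `n_hidden1` for
#'   unstructured families) and `dendrites_per_soma` (or `n_hidden2`). For
#'   `"dense"`, `n_somata` x `dendrites_per_soma` gives `n_hidden1` and
#'   `n_somata` gives `n_hidden2`, so a dense row is node-matched to the
#'   structured row with the same sizes.
#' @param train_data,test_data [image_dataset()]s (or `list(X, y)`).
#' @param n_classes Number of classes.
#' @param config A [train_config()]; its seed is replaced per run.
#' @param seeds Integer vector of run seeds. Default `1:3`.
#' @param rf An [rf_spec()]. Default `rf_spec()`.
#' @param verbose Log progress. Default `FALSE`.
#' @return `data.frame` with one row per run: `model, scheme, n_somata,
#'   dendrites_per_soma, seed, params, epochs_to_min_val_loss, test_loss,
#'   test_acc, f, aes, les`.
#' @export
run_size_grid <- function(families, train_data, test_data, n_classes, config,
                          seeds = 1:3, rf = rf_spec(), verbose = FALSE) {
  stopifnot(is.data.frame(families), inherits(config, "train_config"))
  image_shape <- infer_image_shape(train_data)
  train_data <- as_xy(train_data)
  rows <- list()
  for (r in seq_len(nrow(families))) {
    fam <- families[r, ]
    for (seed in seeds) {
      spec <- grid_model_spec(fam, image_shape, n_classes, rf, seed)
      cfg <- config
      cfg$seed <- as.integer(seed)
      fit <- train(spec, train_data, cfg)
      ev <- evaluate(fit$params, spec, test_data)
      rows[[length(rows) + 1L]] <- data.frame(
        model = sprintf("%s_%dx%d", fam$scheme, fam$n_somata,
                        fam$dendrites_per_soma),
        scheme = fam$scheme, n_somata = fam$n_somata,
        dendrites_per_soma = fam$dendrites_per_soma, seed = seed,
        params = count_trainable_params(spec),
        epochs_to_min_val_loss = epochs_to_min_val_loss(fit$history),
        test_loss = ev$loss, test_acc = ev$accuracy)
      if (verbose) {
        message(sprintf("%s seed %d: acc %.2f loss %.4f",
                        rows[[length(rows)]]$model, seed, ev$accuracy, ev$loss))
      }
    }
  }
  res <- do.call(rbind, rows)
  cohort <- lapply(seq_len(nrow(res)), function(i) {
    efficiency_input(paste0(res$model[i], "_s", res$seed[i]), res$params[i],
                     res$epochs_to_min_val_loss[i], res$test_acc[i],
                     res$test_loss[i])
  })
  res$f <- vapply(cohort, efficiency_factor, numeric(1), cohort = cohort)
  res$aes <- res$test_acc / res$f
  res$les <- res$test_loss * res$f
  res
}

# Build the model spec for one grid row. Dense rows are node-matched to the
# structured rows sharing their sizes.
grid_model_spec <- function(fam, image_shape, n_classes, rf, seed) {
  scheme <- as.character(fam$scheme)
  S <- as.integer(fam$n_somata)
  D <- as.integer(fam$dendrites_per_soma)
  masks <- switch(scheme,
    dense = dense_masks(image_shape, n_hidden1 = S * D, n_hidden2 = S),
    sparse = {
      ref <- dann_masks("LRF", image_shape, S, D, spec = rf, seed = seed)
      dens <- matched_densities(ref)
      random_sparse_masks(image_shape, S * D, S, dens[1L], dens[2L],
                          seed = seed)
    },
    dann_masks(scheme, image_shape, S, D, spec = rf, seed = seed)
  )
  model_spec(masks, n_classes)
}

infer_image_shape <- function(data) {
  shape <- if (inherits(data, "image_dataset")) data$image_shape else
    attr(data, "image_shape")
  if (is.null(shape)) {
    side <- sqrt(ncol(data$X))
    if (side != round(side)) {
      stop("cannot infer image_shape; pass an image_dataset", call. = FALSE)
    }
    shape <- c(side, side, 1L)
  }
  normalize_image_shape(shape)
}
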