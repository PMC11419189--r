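#' Activation hit matrix
#'
#' Counts, per (class, node), the test images of that class on which the
#' node's activation was strictly above zero, and appends one extra row with
#' the number of images (of any class) on which the node stayed inactive.
#' Every column therefore sums exactly to the number of test images, so
#' dividing by it yields the probability matrix behind the node entropy.
#'
#' @param activations Numeric matrix `(n_images x n_nodes)` of a hidden
#'   layer's activations on the test set.
#' @param labels Integer class ids in `[0, n_classes)`, one per image.
#' @param n_classes Number of classes; default `max(labels) + 1`.
#' @return An object of class `hit_matrix`: integer `counts` of shape
#'   `(n_classes + 1) x n_nodes` (last row = inactive counts), `n_images`,
#'   `n_classes`.
#' @export
hit_matrix <- function(activations, labels, n_classes = NULL) {
  assert_finite_matrix(activations, "activations")
  labels <- as.integer(labels)
  if (length(labels) != nrow(activations)) {
    stop("`labels` length must match the rows of `activations`", call. = FALSE)
  }
  n_classes <- n_classes %||% (max(labels) + 1L)
  n_classes <- assert_count(n_classes, "n_classes")
  if (any(labels < 0L | labels >= n_classes)) {
    stop("labels must be integers in [0, n_classes)", call. = FALSE)
  }
  active <- activations > 0
  counts <- matrix(0L, nrow = n_classes + 1L, ncol = ncol(activations))
  for (cl in seq_len(n_classes)) {
    rows <- labels == (cl - 1L)
    counts[cl, ] <- as.integer(colSums(active[rows, , drop = FALSE]))
  }
  counts[n_classes + 1L, ] <- nrow(activations) - as.integer(colSums(active))
  structure(list(counts = counts, n_images = nrow(activations),
                 n_classes = n_classes),
            class = "hit_matrix")
}

#' Node entropy (bits)
#'
#' Shannon entropy of each node's activation profile,
#' `H = -sum p log2 p` with `0 log2 0 := 0`, where `p` is the hit-matrix
#' column (including the inactive row) divided by the number of test images.
#' High entropy marks mixed-selective nodes (active for several classes), low
#' entropy class-specific ones. Nodes that never activate are flagged silent
#' and should be excluded from downstream distributions.
#'
#' @param hm A [hit_matrix()].
#' @return `data.frame` with columns `node`, `entropy` (bits; `NA` for silent
#'   nodes), `silent`.
#' @export
node_entropy <- function(hm) {
  stopifnot(inherits(hm, "hit_matrix"))
  p <- hm$counts / hm$n_images
  ent <- apply(p, 2L, function(col) {
    nz <- col[col > 0]
    -sum(nz * log2(nz))
  })
  silent <- hm$counts[hm$n_classes + 1L, ] == hm$n_images
  ent[silent] <- NA_real_
  data.frame(node = seq_len(ncol(hm$counts)), entropy = ent, silent = silent)
}

#' Selectivity index
#'
#' For each node, the number of classes for which it was active on strictly
#' more than `threshold` test images. A value of 1 denotes class specificity,
#' `n_classes` total mixed selectivity, and 0 a node that never crosses the
#' threshold for any class. The default 400 corresponds to roughly 40% of a
#' 1000-image-per-class test set; [selectivity_threshold()] scales that rule
#' to other test-set sizes.
#'
#' @param hm A [hit_matrix()].
#' @param threshold Non-negative integer count threshold. Default 400.
#' @return `data.frame` with columns `node`, `selectivity` (integer in
#'   `[0, n_classes]`), `active` (crossed the threshold for at least one
#'   class).
#' @export
selectivity_index <- function(hm, threshold = 400L) {
  stopifnot(inherits(hm, "hit_matrix"))
  threshold <- assert_count(threshold, "threshold", min = 0L)
  class_counts <- hm$counts[seq_len(hm$n_classes), , drop = FALSE]
  sel <- as.integer(colSums(class_counts > threshold))
  data.frame(node = seq_len(ncol(hm$counts)), selectivity = sel,
             active = sel > 0L)
}

#' Selectivity threshold scaled to the test-set size
#'
#' `round(0.4 x per-class test count)`: reproduces the 400-image rule for
#' 1000-per-class test sets and scales it proportionally otherwise.
#'
#' @param per_class_test_count Images per class in the test set.
#' @return Integer threshold.
#' @export
selectivity_threshold <- function(per_class_test_count) {
  as.integer(round(0.4 * per_class_test_count))
}

#' Weight distribution statistics
#'
#' Excess (Fisher) kurtosis, Fisher-Pearson skewness and range of a flat
#' weight vector; the statistics summarizing the learned weight distributions.
#' Computed on the raw weights (any kernel-density smoothing is
#' presentation-only).
#'
#' @param weights Numeric vector with at least 4 finite values and nonzero
#'   variance.
#' @return List with `kurtosis`, `skewness`, `range`.
#' @export
weight_stats <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) < 4L || !all(is.finite(weights))) {
    stop("`weights` must hold at least 4 finite values", call. = FALSE)
  }
  if (stats::var(weights) == 0) {
    stop("kurtosis undefined for a constant vector", call. = FALSE)
  }
  list(kurtosis = e1071::kurtosis(weights, type = 1),
       skewness = e1071::skewness(weights, type = 1),
       range = max(weights) - min(weights))
}

#' Weight histogram
#'
#' Equal-width bins spanning `[min, max]`; counts sum to the number of
#' weights. The rightmost bin is closed on both sides so the maximum is
#' counted.
#'
#' @param weights Numeric vector with at least 1 finite value.
#' @param n_bins Number of bins. Default 20.
#' @return List with `edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`).
#' @export
weight_histogram <- function(weights, n_bins = 20L) {
  weights <- as.numeric(weights)
  n_bins <- assert_count(n_bins, "n_bins")
  if (length(weights) < 1L || !all(is.finite(weights))) {
    stop("`weights` must hold at least 1 finite value", call. = FALSE)
  }
  lo <- min(weights); hi <- max(weights)
  if (lo == hi) {
    counts <- integer(n_bins)
    counts[1L] <- length(weights)
    return(list(edges = rep(lo, n_bins + 1L), counts = counts))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(weights, edges, rightmost.closed = TRUE)
  list(edges = edges, counts = tabulate(idx, nbins = n_bins))
}

#' Node-level interpretability report for a trained model
#'
#' Runs the test set through the network, builds a hit matrix per hidden
#' layer, and tabulates entropy, selectivity and the silent flag per node.
#'
#' @param params A `model_params`.
#' @param spec A [model_spec()].
#' @param data Test set (`image_dataset` or `list(X, y)`).
#' @param threshold Selectivity threshold; default scales the 400-image rule
#'   by the per-class test count via [selectivity_threshold()].
#' @return `data.frame` with columns `layer` (`"hidden1"`/`"hidden2"`),
#'   `node`, `entropy`, `selectivity`, `silent`.
#' @export
interpret_model <- function(params, spec, data, threshold = NULL) {
  data <- as_xy(data)
  fw <- forward(params, spec, data$X)
  threshold <- threshold %||%
    selectivity_threshold(length(data$y) / spec$n_classes)
  layer_report <- function(act, layer) {
    hm <- hit_matrix(act, data$y, spec$n_classes)
    ent <- node_entropy(hm)
    sel <- selectivity_index(hm, threshold)
    data.frame(layer = layer, node = ent$node, entropy = ent$entropy,
               selectivity = sel$selectivity, silent = ent$silent)
  }
  rbind(layer_report(fw$a1, "hidden1"), layer_report(fw$a2, "hidden2"))
}
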