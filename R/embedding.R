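#' Embed hidden activations in two dimensions
#'
#' Draws a seeded random subset of the activations, runs t-distributed
#' stochastic neighbor embedding (via \pkg{Rtsne}) with the study's protocol
#' (2-D output, perplexity 50, default subset of 2000 test observations), and
#' returns the coordinates aligned with their class labels so the projection
#' quality scores can be computed on them.
#'
#' @param activations Numeric matrix `(n x n_nodes)` of hidden activations.
#' @param labels Integer class ids aligned with the rows of `activations`.
#' @param subset_size Number of observations to embed. Default
#'   `min(2000, n)`.
#' @param perplexity t-SNE perplexity. Default 50; must satisfy
#'   `3 * perplexity < subset_size - 1`.
#' @param seed Integer seed controlling both the subset draw and the
#'   embedding.
#' @param max_iter t-SNE iterations. Default 1000.
#' @return An object of class `embedding_run`: `coords`
#'   (`subset_size x 2`), `labels`, `indices` (rows embedded), `perplexity`,
#'   `seed`.
#' @export
embed_activations <- function(activations, labels, subset_size = NULL,
                              perplexity = 50, seed = 1L, max_iter = 1000L) {
  assert_finite_matrix(activations, "activations")
  labels <- as.integer(labels)
  n <- nrow(activations)
  if (length(labels) != n) {
    stop("`labels` length must match the rows of `activations`", call. = FALSE)
  }
  subset_size <- subset_size %||% min(2000L, n)
  subset_size <- assert_count(subset_size, "subset_size")
  if (subset_size > n) {
    stop("`subset_size` exceeds the number of observations", call. = FALSE)
  }
  if (perplexity >= subset_size) {
    stop("`perplexity` must be smaller than `subset_size`", call. = FALSE)
  }
  if (3 * perplexity >= subset_size - 1) {
    stop("t-SNE requires 3 * perplexity < subset_size - 1", call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(n, subset_size))
  coords <- with_seed(seed, {
    Rtsne::Rtsne(activations[idx, , drop = FALSE], dims = 2,
                 perplexity = perplexity, max_iter = max_iter,
                 check_duplicates = FALSE, pca = FALSE, verbose = FALSE)$Y
  })
  structure(list(coords = coords, labels = labels[idx], indices = idx,
                 perplexity = perplexity, seed = seed),
            class = "embedding_run")
}

# Pairwise Euclidean distance matrix with an exact zero diagonal.
euclid_dist <- function(x) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- 0
  d
}

# Indices of the k nearest neighbors of each point (self excluded), ties in
# distance broken by ascending point index (order() is stable).
knn_indices <- function(d, k) {
  n <- nrow(d)
  res <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]
    ord[seq_len(k)]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Mean silhouette score
#'
#' For each sample, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own class and `b` the smallest mean distance to any other class
#' (Euclidean); the score is the average over samples and lies in `[-1, 1]`.
#' Values near 1 indicate well-separated classes, near 0 overlapping ones.
#'
#' @param coords Numeric matrix of point coordinates.
#' @param labels Class ids aligned with `coords`; at least 2 classes.
#' @param singleton How to score a sample whose class has a single member:
#'   `"zero"` (default, `s := 0`) or `"error"`.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_score <- function(coords, labels, singleton = c("zero", "error")) {
  singleton <- match.arg(singleton)
  coords <- as.matrix(coords)
  labels <- as.vector(labels)
  if (length(labels) != nrow(coords)) {
    stop("`labels` length must match the rows of `coords`", call. = FALSE)
  }
  classes <- unique(labels)
  if (length(classes) < 2L) {
    stop("silhouette needs at least 2 classes", call. = FALSE)
  }
  d <- euclid_dist(coords)
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      if (singleton == "error") {
        stop("class with a single point", call. = FALSE)
      }
      s[i] <- 0
      next
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(classes, labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    denom <- max(a, b)
    s[i] <- if (denom == 0) 0 else (b - a) / denom
  }
  mean(s)
}

#' Neighborhood hit score
#'
#' Mean, over all points, of the fraction of a point's `k` nearest neighbors
#' (Euclidean, self excluded, distance ties broken by ascending index) that
#' share its class label. Bounded in `[0, 1]`; measures local class
#' separation of an embedding.
#'
#' @param coords Numeric matrix of embedded coordinates.
#' @param labels Class ids aligned with `coords`.
#' @param k Neighborhood size; default 11. Must satisfy `k < n`.
#' @return Score in `[0, 1]`.
#' @export
neighborhood_hit <- function(coords, labels, k = 11L) {
  coords <- as.matrix(coords)
  labels <- as.vector(labels)
  k <- assert_count(k, "k")
  n <- nrow(coords)
  if (length(labels) != n) {
    stop("`labels` length must match the rows of `coords`", call. = FALSE)
  }
  if (k >= n) stop("`k` must be smaller than the number of points", call. = FALSE)
  nn <- knn_indices(euclid_dist(coords), k)
  mean(vapply(seq_len(n), function(i) {
    mean(labels[nn[i, ]] == labels[i])
  }, numeric(1)))
}

#' Trustworthiness of a low-dimensional projection
#'
#' `T(k) = 1 - 2 / (n k (2n - 3k - 1)) * sum_i sum_{j in N_i^k}
#' max(0, r(i, j) - k)`, where `N_i^k` are the `k` nearest neighbors of `i`
#' in the low-dimensional space that are not among its `k` nearest neighbors
#' in the high-dimensional space, and `r(i, j)` is the rank of `j` by
#' distance from `i` in the high-dimensional space (self excluded, ties by
#' ascending index). Bounded in `[0, 1]`; values near 1 mean the projection
#' introduced no unexpected neighbors, i.e. local structure was retained.
#'
#' @param high_dim Numeric matrix of original coordinates.
#' @param low_dim Numeric matrix of projected coordinates; same row count.
#' @param k Neighborhood size; default 11. Needs `2n - 3k - 1 > 0`.
#' @return Score in `[0, 1]`.
#' @export
trustworthiness <- function(high_dim, low_dim, k = 11L) {
  high_dim <- as.matrix(high_dim)
  low_dim <- as.matrix(low_dim)
  k <- assert_count(k, "k")
  n <- nrow(high_dim)
  if (nrow(low_dim) != n) {
    stop("`high_dim` and `low_dim` must have the same number of rows",
         call. = FALSE)
  }
  if (2 * n - 3 * k - 1 <= 0) {
    stop("degenerate normalization: need 2n - 3k - 1 > 0", call. = FALSE)
  }
  dh <- euclid_dist(high_dim)
  dl <- euclid_dist(low_dim)
  nn_low <- knn_indices(dl, k)
  penalty <- 0
  for (i in seq_len(n)) {
    ord_h <- order(dh[i, ])
    ord_h <- ord_h[ord_h != i]
    rank_h <- integer(n)
    rank_h[ord_h] <- seq_len(n - 1L)
    unexpected <- setdiff(nn_low[i, ], ord_h[seq_len(k)])
    penalty <- penalty + sum(pmax(0, rank_h[unexpected] - k))
  }
  1 - 2 * penalty / (n * k * (2 * n - 3 * k - 1))
}

#' Projection-quality scores of an embedding run
#'
#' Convenience wrapper computing silhouette, neighborhood hit and
#' trustworthiness (the latter against the high-dimensional activations the
#' run embedded) for one [embed_activations()] result.
#'
#' @param run An `embedding_run`.
#' @param activations The activation matrix the run was built from.
#' @param k Neighborhood size for NH and trustworthiness. Default 11.
#' @return `data.frame` with one row: `silhouette`, `neighborhood_hit`,
#'   `trustworthiness`.
#' @export
embedding_scores <- function(run, activations, k = 11L) {
  stopifnot(inherits(run, "embedding_run"))
  high <- activations[run$indices, , drop = FALSE]
  data.frame(
    silhouette = silhouette_score(run$coords, run$labels),
    neighborhood_hit = neighborhood_hit(run$coords, run$labels, k),
    trustworthiness = trustworthiness(high, run$coords, k)
  )
}
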