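# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately loop-based and naive; the package implementations are
# checked against these, never the other way round.

# per-image, per-class tally of active nodes (activation strictly > 0)
hit_matrix_oracle <- function(activations, labels, n_classes) {
  counts <- matrix(0L, n_classes + 1L, ncol(activations))
  for (img in seq_len(nrow(activations))) {
    for (node in seq_len(ncol(activations))) {
      if (activations[img, node] > 0) {
        counts[labels[img] + 1L, node] <- counts[labels[img] + 1L, node] + 1L
      } else {
        counts[n_classes + 1L, node] <- counts[n_classes + 1L, node] + 1L
      }
    }
  }
  counts
}

entropy_oracle <- function(counts_col, n_images) {
  h <- 0
  for (c in counts_col) {
    p <- c / n_images
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

silhouette_oracle <- function(coords, labels) {
  n <- nrow(coords)
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(sapply(own, d, i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(sapply(which(labels == cl), d, i = i)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

nh_oracle <- function(coords, labels, k) {
  n <- nrow(coords)
  hits <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt(colSums((t(coords) - coords[i, ])^2))
    ord <- order(dd)          # stable: ties by ascending index
    ord <- ord[ord != i][seq_len(k)]
    hits[i] <- mean(labels[ord] == labels[i])
  }
  mean(hits)
}

trustworthiness_oracle <- function(high, low, k) {
  n <- nrow(high)
  dist_to <- function(x, i) sqrt(colSums((t(x) - x[i, ])^2))
  penalty <- 0
  for (i in seq_len(n)) {
    oh <- order(dist_to(high, i)); oh <- oh[oh != i]
    ol <- order(dist_to(low, i)); ol <- ol[ol != i]
    knn_h <- oh[seq_len(k)]
    knn_l <- ol[seq_len(k)]
    for (j in knn_l) {
      if (!(j %in% knn_h)) {
        r <- which(oh == j)
        penalty <- penalty + max(0, r - k)
      }
    }
  }
  1 - 2 * penalty / (n * k * (2 * n - 3 * k - 1))
}

# tiny labelled Gaussian blobs in arbitrary dimension
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(cl) {
    matrix(stats::rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[cl, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(X = X, y = rep(seq_len(nrow(centers)) - 1L, each = n_per))
}

# small cached synthetic dataset shared across unit tests (not the
# acceptance-study dataset)
tiny_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_synthetic(train_per_class = 30L, test_per_class = 15L,
                               seed = 42L)
    }
    cache
  }
})

# 1-nearest-neighbour classifier on raw pixels (baseline)
nn1_predict <- function(Xtr, ytr, Xte) {
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  ytr[max.col(-d2, ties.method = "first")]
}

# reference Adam/cross-entropy trainer in numpy, run through the system
# python; returns the final parameter list after `steps` full-batch steps
run_numpy_adam_reference <- function(X, Y, params, cfg, steps, slope = 0.1) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  wr <- function(m, name) utils::write.table(
    m, file.path(dir, paste0(name, ".csv")), sep = ",",
    row.names = FALSE, col.names = FALSE)
  wr(X, "X"); wr(Y, "Y")
  for (k in names(params)) wr(params[[k]], k)
  script <- file.path(dir, "ref.py")
  writeLines(sprintf('
import numpy as np, os
d = %s
ld = lambda f: np.loadtxt(os.path.join(d, f + ".csv"), delimiter=",", ndmin=2)
X, Y = ld("X"), ld("Y")
W1, W2, W3 = ld("W1"), ld("W2"), ld("W3")
b1, b2, b3 = ld("b1").ravel(), ld("b2").ravel(), ld("b3").ravel()
lr, be1, be2, eps, slope = %.17g, %.17g, %.17g, %.17g, %.17g
params = [W1, b1, W2, b2, W3, b3]
m = [np.zeros_like(p) for p in params]
v = [np.zeros_like(p) for p in params]
lrelu = lambda z: np.where(z > 0, z, slope * z)
dlrelu = lambda z: np.where(z > 0, 1.0, slope)
n = X.shape[0]
for t in range(1, %d + 1):
    W1, b1, W2, b2, W3, b3 = params
    z1 = X @ W1 + b1; a1 = lrelu(z1)
    z2 = a1 @ W2 + b2; a2 = lrelu(z2)
    z3 = a2 @ W3 + b3
    zs = z3 - z3.max(axis=1, keepdims=True)
    p = np.exp(zs); p /= p.sum(axis=1, keepdims=True)
    dz3 = (p - Y) / n
    g = [None] * 6
    g[4] = a2.T @ dz3; g[5] = dz3.sum(axis=0)
    dz2 = (dz3 @ W3.T) * dlrelu(z2)
    g[2] = a1.T @ dz2; g[3] = dz2.sum(axis=0)
    dz1 = (dz2 @ W2.T) * dlrelu(z1)
    g[0] = X.T @ dz1; g[1] = dz1.sum(axis=0)
    for i in range(6):
        m[i] = be1 * m[i] + (1 - be1) * g[i]
        v[i] = be2 * v[i] + (1 - be2) * g[i] ** 2
        params[i] = params[i] - lr * (m[i] / (1 - be1 ** t)) / (
            np.sqrt(v[i] / (1 - be2 ** t)) + eps)
for name, p in zip(["W1", "b1", "W2", "b2", "W3", "b3"], params):
    np.savetxt(os.path.join(d, "out_" + name + ".csv"), np.atleast_2d(p),
               delimiter=",")
', deparse(dir), cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$epsilon,
    slope, steps), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  rd <- function(name) as.matrix(utils::read.table(
    file.path(dir, paste0("out_", name, ".csv")), sep = ","))
  out <- list(W1 = rd("W1"), b1 = as.numeric(rd("b1")),
              W2 = rd("W2"), b2 = as.numeric(rd("b2")),
              W3 = rd("W3"), b3 = as.numeric(rd("b3")))
  lapply(out, unname)
}
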