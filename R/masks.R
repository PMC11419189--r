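#' Receptive-field specification
#'
#' Describes how a dendrite samples the input image: the size of the
#' rectangular window it draws pixels from, how many pixel locations it
#' samples, and (for the global-receptive-field scheme) how far a dendrite's
#' window center may be jittered away from its soma's center.
#'
#' @param window_shape Integer pair `(rows, cols)` of the sampling window.
#'   Default `c(4, 4)`.
#' @param synapses_per_dendrite Number of pixel locations each dendrite
#'   samples. Default 16, the full 4x4 window. Must not exceed the window
#'   area (in pixel locations).
#' @param grf_spread Non-negative integer Chebyshev radius (in pixels) of the
#'   square from which each dendrite's window anchor is drawn around its
#'   soma's anchor, in the global-receptive-field scheme. Default 2.
#' @return An object of class `rf_spec`.
#' @export
rf_spec <- function(window_shape = c(4L, 4L), synapses_per_dendrite = 16L,
                    grf_spread = 2L) {
  window_shape <- c(assert_count(window_shape[1L], "window_shape[1]"),
                    assert_count(window_shape[2L], "window_shape[2]"))
  synapses_per_dendrite <- assert_count(synapses_per_dendrite,
                                        "synapses_per_dendrite")
  grf_spread <- assert_count(grf_spread, "grf_spread", min = 0L)
  if (synapses_per_dendrite > prod(window_shape)) {
    stop("`synapses_per_dendrite` exceeds the window area", call. = FALSE)
  }
  structure(list(window_shape = window_shape,
                 synapses_per_dendrite = synapses_per_dendrite,
                 grf_spread = grf_spread),
            class = "rf_spec")
}

new_mask_pair <- function(input_mask, structure_mask, scheme, image_shape,
                          spec = NULL, seed = NULL) {
  structure(list(input_mask = input_mask,
                 structure_mask = structure_mask,
                 scheme = scheme,
                 image_shape = image_shape,
                 spec = spec,
                 seed = seed),
            class = "mask_pair")
}

#' @export
print.mask_pair <- function(x, ...) {
  cat(sprintf("<mask_pair scheme=%s> input %d x %d (%d on), structure %d x %d (%d on)\n",
              x$scheme, nrow(x$input_mask), ncol(x$input_mask),
              sum(x$input_mask), nrow(x$structure_mask),
              ncol(x$structure_mask), sum(x$structure_mask)))
  invisible(x)
}

#' Dendro-somatic structure mask
#'
#' Builds the boolean mask of the second hidden layer: each dendrite is wired
#' to exactly one soma, in contiguous blocks, so rows `[(s-1)*D + 1, s*D]` are
#' true only in column `s`. This tree-like mask is what makes the network
#' "dendritic" rather than generically sparse.
#'
#' @param n_somata Number of somatic (second hidden layer) units.
#' @param dendrites_per_soma Number of dendrites wired to each soma.
#' @return Logical matrix of shape
#'   `(n_somata * dendrites_per_soma) x n_somata`.
#' @examples
#' m <- build_structure_mask(2, 3)
#' colSums(m)  # 3 3
#' @export
build_structure_mask <- function(n_somata, dendrites_per_soma) {
  n_somata <- assert_count(n_somata, "n_somata")
  dendrites_per_soma <- assert_count(dendrites_per_soma, "dendrites_per_soma")
  m <- matrix(FALSE, nrow = n_somata * dendrites_per_soma, ncol = n_somata)
  soma_of_dendrite <- rep(seq_len(n_somata), each = dendrites_per_soma)
  m[cbind(seq_len(nrow(m)), soma_of_dendrite)] <- TRUE
  m
}

# Expand a set of sampled pixel locations (row, col) to feature indices,
# taking all channels at each location.
locations_to_features <- function(rows, cols, image_shape) {
  ch <- image_shape[3L]
  as.vector(vapply(seq_len(ch), function(k) {
    pixel_index(rows, cols, k, image_shape)
  }, integer(length(rows))))
}

#' Random input sampling (dANN-R)
#'
#' Each dendrite receives `synapses_per_dendrite` inputs drawn uniformly
#' without replacement from the whole image. For multi-channel images a drawn
#' pixel location contributes all of its channels.
#'
#' @param image_shape `(height, width)` or `(height, width, channels)`.
#' @param n_dendrites_total Number of dendritic units (columns of the mask).
#' @param spec An [rf_spec()].
#' @param seed Integer seed; the construction is a pure function of
#'   `(arguments, seed)`.
#' @return Logical matrix `(n_features x n_dendrites_total)`.
#' @export
sample_random_inputs <- function(image_shape, n_dendrites_total,
                                 spec = rf_spec(), seed = 1L) {
  image_shape <- normalize_image_shape(image_shape)
  n_dendrites_total <- assert_count(n_dendrites_total, "n_dendrites_total")
  n_loc <- image_shape[1L] * image_shape[2L]
  k <- spec$synapses_per_dendrite
  if (k > n_loc) {
    stop("`synapses_per_dendrite` exceeds the number of pixel locations",
         call. = FALSE)
  }
  n_feat <- n_features_of(image_shape)
  mask <- matrix(FALSE, nrow = n_feat, ncol = n_dendrites_total)
  with_seed(seed, {
    for (d in seq_len(n_dendrites_total)) {
      loc <- sample.int(n_loc, k)                 # 1-based location index
      rows <- (loc - 1L) %/% image_shape[2L] + 1L
      cols <- (loc - 1L) %% image_shape[2L] + 1L
      mask[locations_to_features(rows, cols, image_shape), d] <- TRUE
    }
  })
  mask
}

# Draw one uniform window anchor (top-left corner); valid anchors keep the
# whole window inside the image.
valid_anchor_range <- function(image_shape, window_shape) {
  hr <- image_shape[1L] - window_shape[1L] + 1L
  wr <- image_shape[2L] - window_shape[2L] + 1L
  if (hr < 1L || wr < 1L) {
    stop("receptive-field window is larger than the image", call. = FALSE)
  }
  c(hr, wr)
}

window_features <- function(anchor_row, anchor_col, spec, image_shape) {
  wr <- spec$window_shape[1L]; wc <- spec$window_shape[2L]
  grid <- expand.grid(row = anchor_row + seq_len(wr) - 1L,
                      col = anchor_col + seq_len(wc) - 1L)
  k <- spec$synapses_per_dendrite
  if (k < nrow(grid)) {
    keep <- sample.int(nrow(grid), k)
    grid <- grid[keep, , drop = FALSE]
  }
  locations_to_features(grid$row, grid$col, image_shape)
}

#' Local receptive field sampling (dANN-LRF)
#'
#' Each dendrite samples a spatially restricted part of the image: a window
#' anchor is drawn uniformly over all positions where the window fits inside
#' the image, and the dendrite's inputs are the `synapses_per_dendrite` pixel
#' locations of that window (for the default 4x4 window and 16 synapses, the
#' entire contiguous patch).
#'
#' @inheritParams sample_random_inputs
#' @return Logical matrix `(n_features x n_dendrites_total)`.
#' @export
sample_lrf <- function(image_shape, n_dendrites_total, spec = rf_spec(),
                       seed = 1L) {
  image_shape <- normalize_image_shape(image_shape)
  n_dendrites_total <- assert_count(n_dendrites_total, "n_dendrites_total")
  rng <- valid_anchor_range(image_shape, spec$window_shape)
  n_feat <- n_features_of(image_shape)
  mask <- matrix(FALSE, nrow = n_feat, ncol = n_dendrites_total)
  with_seed(seed, {
    for (d in seq_len(n_dendrites_total)) {
      ar <- sample.int(rng[1L], 1L)
      ac <- sample.int(rng[2L], 1L)
      mask[window_features(ar, ac, spec, image_shape), d] <- TRUE
    }
  })
  mask
}

#' Global receptive field sampling (dANN-GRF)
#'
#' One window anchor is drawn per soma (uniform over valid anchors); each of
#' its dendrites then gets an anchor drawn uniformly from the square of side
#' `2 * grf_spread + 1` around the somatic anchor, clipped to the valid anchor
#' range, and samples its window as in [sample_lrf()]. With `grf_spread = 0`
#' all dendrites of a soma share the identical window.
#'
#' @inheritParams sample_random_inputs
#' @param n_somata Number of somata.
#' @param dendrites_per_soma Dendrites per soma; dendrite columns are ordered
#'   soma-block-wise to match [build_structure_mask()].
#' @return Logical matrix `(n_features x n_somata * dendrites_per_soma)`.
#' @export
sample_grf <- function(image_shape, n_somata, dendrites_per_soma,
                       spec = rf_spec(), seed = 1L) {
  image_shape <- normalize_image_shape(image_shape)
  n_somata <- assert_count(n_somata, "n_somata")
  dendrites_per_soma <- assert_count(dendrites_per_soma, "dendrites_per_soma")
  rng <- valid_anchor_range(image_shape, spec$window_shape)
  n_feat <- n_features_of(image_shape)
  mask <- matrix(FALSE, nrow = n_feat, ncol = n_somata * dendrites_per_soma)
  spread <- spec$grf_spread
  with_seed(seed, {
    for (s in seq_len(n_somata)) {
      sr <- sample.int(rng[1L], 1L)
      sc <- sample.int(rng[2L], 1L)
      for (j in seq_len(dendrites_per_soma)) {
        ar <- sr + sample.int(2L * spread + 1L, 1L) - spread - 1L
        ac <- sc + sample.int(2L * spread + 1L, 1L) - spread - 1L
        ar <- min(max(ar, 1L), rng[1L])
        ac <- min(max(ac, 1L), rng[2L])
        d <- (s - 1L) * dendrites_per_soma + j
        mask[window_features(ar, ac, spec, image_shape), d] <- TRUE
      }
    }
  })
  mask
}

#' Build the mask pair for a dendritic network
#'
#' Convenience constructor tying input sampling and dendro-somatic structure
#' together for the dANN schemes. Scheme `"F"` (all-to-all input sampling)
#' keeps the structured second layer but an all-true input mask.
#'
#' @param scheme One of `"R"`, `"LRF"`, `"GRF"`, `"F"`.
#' @param image_shape `(height, width)` or `(height, width, channels)`.
#' @param n_somata,dendrites_per_soma Network size.
#' @param spec An [rf_spec()].
#' @param seed Integer seed.
#' @return A `mask_pair`.
#' @examples
#' mp <- dann_masks("LRF", c(28, 28), n_somata = 4, dendrites_per_soma = 8)
#' colSums(mp$input_mask)[1]  # 16
#' @export
dann_masks <- function(scheme = c("LRF", "R", "GRF", "F"), image_shape,
                       n_somata, dendrites_per_soma, spec = rf_spec(),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  image_shape <- normalize_image_shape(image_shape)
  n_somata <- assert_count(n_somata, "n_somata")
  dendrites_per_soma <- assert_count(dendrites_per_soma, "dendrites_per_soma")
  n_dend <- n_somata * dendrites_per_soma
  input_mask <- switch(scheme,
    R = sample_random_inputs(image_shape, n_dend, spec, seed),
    LRF = sample_lrf(image_shape, n_dend, spec, seed),
    GRF = sample_grf(image_shape, n_somata, dendrites_per_soma, spec, seed),
    F = matrix(TRUE, nrow = n_features_of(image_shape), ncol = n_dend)
  )
  new_mask_pair(input_mask, build_structure_mask(n_somata, dendrites_per_soma),
                scheme, image_shape, spec = spec, seed = seed)
}

#' Randomly connected sparse masks (sANN)
#'
#' Builds the comparator wiring: boolean masks with the requested fraction of
#' true entries placed uniformly at random (without duplicate edges) and no
#' structural constraint. With both densities equal to 1 the wiring is fully
#' connected, identical to a vanilla ANN.
#'
#' @param image_shape `(height, width)` or `(height, width, channels)`.
#' @param n_hidden1,n_hidden2 Hidden layer widths.
#' @param density1,density2 Fractions of true entries in layers 1 and 2, in
#'   `(0, 1]`. To match a reference dendritic network's nonzero counts use
#'   [matched_densities()].
#' @param seed Integer seed.
#' @return A `mask_pair` with scheme `"SPARSE_RANDOM"`.
#' @export
random_sparse_masks <- function(image_shape, n_hidden1, n_hidden2,
                                density1, density2, seed = 1L) {
  image_shape <- normalize_image_shape(image_shape)
  n_hidden1 <- assert_count(n_hidden1, "n_hidden1")
  n_hidden2 <- assert_count(n_hidden2, "n_hidden2")
  for (d in c(density1, density2)) {
    if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0 || d > 1) {
      stop("densities must lie in (0, 1]", call. = FALSE)
    }
  }
  n_feat <- n_features_of(image_shape)
  fill <- function(nr, nc, density) {
    m <- matrix(FALSE, nr, nc)
    n_on <- round(density * nr * nc)
    m[sample.int(nr * nc, n_on)] <- TRUE
    m
  }
  with_seed(seed, {
    m1 <- fill(n_feat, n_hidden1, density1)
    m2 <- fill(n_hidden1, n_hidden2, density2)
    new_mask_pair(m1, m2, "SPARSE_RANDOM", image_shape, seed = seed)
  })
}

#' Densities matching a reference mask pair's nonzero counts
#'
#' @param masks A `mask_pair` (typically a dANN's).
#' @return Numeric pair `(density1, density2)` such that
#'   [random_sparse_masks()] places exactly as many true entries per layer as
#'   `masks` has.
#' @export
matched_densities <- function(masks) {
  stopifnot(inherits(masks, "mask_pair"))
  c(sum(masks$input_mask) / length(masks$input_mask),
    sum(masks$structure_mask) / length(masks$structure_mask))
}

#' Fully connected (vanilla) mask pair
#'
#' All-true masks for a dense two-hidden-layer comparator (vANN): every mask
#' operation becomes the identity, so the network is an ordinary multilayer
#' perceptron.
#'
#' @inheritParams random_sparse_masks
#' @return A `mask_pair` with scheme `"F_DENSE"`.
#' @export
dense_masks <- function(image_shape, n_hidden1, n_hidden2) {
  image_shape <- normalize_image_shape(image_shape)
  n_feat <- n_features_of(image_shape)
  new_mask_pair(matrix(TRUE, n_feat, n_hidden1),
                matrix(TRUE, n_hidden1, n_hidden2),
                "F_DENSE", image_shape)
}

#' Save / load a mask pair
#'
#' Serializes the two boolean arrays plus a header (scheme, image shape, seed,
#' receptive-field spec) to a single compressed archive; the round trip is
#' bit-exact.
#'
#' @param masks A `mask_pair`.
#' @param path File path (conventionally `.rds`).
#' @return `write_masks` returns `path` invisibly; `read_masks` the
#'   `mask_pair`.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "mask_pair"))
  saveRDS(masks, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "mask_pair")) stop("not a mask archive", call. = FALSE)
  x
}
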