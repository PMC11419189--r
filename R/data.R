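#' Image dataset container
#'
#' Flat feature matrix plus labels and the image geometry needed to map
#' feature columns back to pixels. The package-wide flattening convention is
#' row-major, channel-last: feature index
#' `((row - 1) * width + (col - 1)) * channels + channel`, 1-based.
#'
#' @param X Numeric matrix `(n x n_features)` with intensities in `[0, 1]`.
#' @param y Integer class ids in `[0, n_classes)`.
#' @param image_shape `(height, width)` or `(height, width, channels)`.
#' @param split Optional tag: `"train"`, `"val"` or `"test"`.
#' @return An object of class `image_dataset`.
#' @export
image_dataset <- function(X, y, image_shape, split = NA_character_) {
  image_shape <- normalize_image_shape(image_shape)
  if (!is.matrix(X) || ncol(X) != n_features_of(image_shape)) {
    stop("`X` must be a matrix with prod(image_shape) columns", call. = FALSE)
  }
  if (min(X) < 0 || max(X) > 1) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("|y| must equal nrow(X)", call. = FALSE)
  structure(list(X = X, y = y, image_shape = image_shape, split = split),
            class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset%s> %d images %dx%dx%d, %d classes\n",
              if (is.na(x$split)) "" else paste0(" ", x$split),
              nrow(x$X), x$image_shape[1L], x$image_shape[2L],
              x$image_shape[3L], length(unique(x$y))))
  invisible(x)
}

read_be_int <- function(con, path, what) {
  v <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(v) != 1L) {
    stop(sprintf("truncated IDX file '%s' while reading %s", path, what),
         call. = FALSE)
  }
  v
}

#' Read an IDX (MNIST-family) image/label file pair
#'
#' Parses the big-endian IDX format (magic `0x00000803` for images,
#' `0x00000801` for labels), transparently decompressing gzip. Pixel bytes in
#' `[0, 255]` are scaled to `[0, 1]` and flattened row-major.
#'
#' @param images_path Path to the images file (`.idx3-ubyte`, optionally
#'   `.gz`).
#' @param labels_path Path to the labels file (`.idx1-ubyte`, optionally
#'   `.gz`).
#' @param split Optional split tag for the returned dataset.
#' @return An [image_dataset()].
#' @export
read_idx <- function(images_path, labels_path, split = NA_character_) {
  for (p in c(images_path, labels_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: '%s'", p), call. = FALSE)
  }
  icon <- gzfile(images_path, "rb"); on.exit(close(icon), add = TRUE)
  magic <- read_be_int(icon, images_path, "magic number (offset 0)")
  if (magic != 2051L) {
    stop(sprintf("'%s': bad image magic number 0x%08x at byte offset 0",
                 images_path, magic), call. = FALSE)
  }
  n <- read_be_int(icon, images_path, "image count")
  h <- read_be_int(icon, images_path, "row count")
  w <- read_be_int(icon, images_path, "column count")
  pix <- readBin(icon, "integer", n = n * h * w, size = 1L, signed = FALSE)
  if (length(pix) != n * h * w) {
    stop(sprintf("'%s': truncated pixel data at byte offset %d",
                 images_path, 16L + length(pix)), call. = FALSE)
  }
  lcon <- gzfile(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- read_be_int(lcon, labels_path, "magic number (offset 0)")
  if (lmagic != 2049L) {
    stop(sprintf("'%s': bad label magic number 0x%08x at byte offset 0",
                 labels_path, lmagic), call. = FALSE)
  }
  nl <- read_be_int(lcon, labels_path, "label count")
  if (nl != n) {
    stop(sprintf("image/label count mismatch: %d images vs %d labels", n, nl),
         call. = FALSE)
  }
  y <- readBin(lcon, "integer", n = nl, size = 1L, signed = FALSE)
  if (length(y) != nl) {
    stop(sprintf("'%s': truncated label data at byte offset %d",
                 labels_path, 8L + length(y)), call. = FALSE)
  }
  # IDX stores each image row-major; filling the matrix by row reproduces the
  # package's row-major flattening for single-channel images.
  X <- matrix(pix / 255, nrow = n, ncol = h * w, byrow = TRUE)
  image_dataset(X, y, c(h, w, 1L), split = split)
}

#' Write an [image_dataset()] as an IDX file pair
#'
#' Fixture/export writer (single-channel only); the inverse of [read_idx()].
#' Intensities are scaled back to bytes with `round(x * 255)`.
#'
#' @param dataset An [image_dataset()] with 1 channel.
#' @param images_path,labels_path Output paths; a `.gz` suffix triggers gzip
#'   compression.
#' @return Invisibly, `c(images_path, labels_path)`.
#' @export
write_idx <- function(dataset, images_path, labels_path) {
  stopifnot(inherits(dataset, "image_dataset"))
  if (dataset$image_shape[3L] != 1L) {
    stop("IDX export supports single-channel images only", call. = FALSE)
  }
  open_out <- function(p) if (grepl("\\.gz$", p)) gzfile(p, "wb") else file(p, "wb")
  h <- dataset$image_shape[1L]; w <- dataset$image_shape[2L]
  n <- nrow(dataset$X)
  icon <- open_out(images_path); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, n, h, w), icon, size = 4L, endian = "big")
  writeBin(as.raw(round(t(dataset$X) * 255)), icon)
  lcon <- open_out(labels_path); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, n), lcon, size = 4L, endian = "big")
  writeBin(as.raw(dataset$y), lcon)
  invisible(c(images_path, labels_path))
}

# Class template centers on a grid with enough margin that blob + maximal
# jitter stays inside the image.
synthetic_centers <- function(n_classes, image_shape, margin) {
  h <- image_shape[1L]; w <- image_shape[2L]
  if (2 * margin + 1 > min(h, w)) {
    stop("blob does not fit in the image after maximal jitter", call. = FALSE)
  }
  nr <- max(1L, floor(sqrt(n_classes)))
  nc <- ceiling(n_classes / nr)
  rows <- round(seq(margin + 1L, h - margin, length.out = nr))
  cols <- round(seq(margin + 1L, w - margin, length.out = nc))
  grid <- expand.grid(row = rows, col = cols)
  grid[seq_len(n_classes), , drop = FALSE]
}

render_blob <- function(center_row, center_col, image_shape, blob_radius) {
  h <- image_shape[1L]; w <- image_shape[2L]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- exp(-((rr - center_row)^2 + (cc - center_col)^2) / (2 * blob_radius^2))
  as.vector(t(img))  # row-major flattening
}

#' Generate a synthetic class-structured image dataset
#'
#' Emulates MNIST-family data at desk scale with spatially localized class
#' information, so that restricted (receptive-field) input sampling has
#' signal to exploit. Each class has a fixed template: a Gaussian intensity
#' blob at a class-specific center on a grid. Each sample is the template
#' shifted by an integer jitter drawn uniformly in
#' `[-within_class_jitter, within_class_jitter]` per axis, plus i.i.d.
#' `N(0, pixel_noise_sd^2)` pixel noise, clipped to `[0, 1]`. Classes are
#' balanced; train and test are disjoint draws; everything is a pure function
#' of the spec and seed.
#'
#' @param n_classes Number of classes. Default 10.
#' @param train_per_class,test_per_class Images per class. Defaults 200
#'   and 100.
#' @param image_shape Image geometry. Default `c(28, 28, 1)`.
#' @param blob_radius Gaussian sd (pixels) of the intensity blob. Default 2.5.
#' @param within_class_jitter Maximal per-axis shift (pixels). Default 2.
#' @param pixel_noise_sd Additive Gaussian pixel noise sd on the `[0, 1]`
#'   intensity scale. Default 0.1.
#' @param seed Integer seed.
#' @return List with `train` and `test` [image_dataset()]s and `centers`
#'   (per-class template centers).
#' @export
make_synthetic <- function(n_classes = 10L, train_per_class = 200L,
                           test_per_class = 100L, image_shape = c(28L, 28L, 1L),
                           blob_radius = 2.5, within_class_jitter = 2L,
                           pixel_noise_sd = 0.1, seed = 1L) {
  n_classes <- assert_count(n_classes, "n_classes")
  train_per_class <- assert_count(train_per_class, "train_per_class")
  test_per_class <- assert_count(test_per_class, "test_per_class")
  image_shape <- normalize_image_shape(image_shape)
  if (image_shape[3L] != 1L) {
    stop("the synthetic generator produces single-channel images", call. = FALSE)
  }
  within_class_jitter <- assert_count(within_class_jitter,
                                      "within_class_jitter", min = 0L)
  stopifnot(blob_radius > 0, pixel_noise_sd >= 0)
  margin <- ceiling(2 * blob_radius) + within_class_jitter
  centers <- synthetic_centers(n_classes, image_shape, margin)

  draw_split <- function(per_class, tag) {
    n <- n_classes * per_class
    X <- matrix(0, n, n_features_of(image_shape))
    y <- integer(n)
    i <- 0L
    for (cl in seq_len(n_classes)) {
      for (s in seq_len(per_class)) {
        i <- i + 1L
        jr <- sample.int(2L * within_class_jitter + 1L, 1L) -
          within_class_jitter - 1L
        jc <- sample.int(2L * within_class_jitter + 1L, 1L) -
          within_class_jitter - 1L
        img <- render_blob(centers$row[cl] + jr, centers$col[cl] + jc,
                           image_shape, blob_radius)
        if (pixel_noise_sd > 0) {
          img <- img + stats::rnorm(length(img), 0, pixel_noise_sd)
        }
        X[i, ] <- pmin(pmax(img, 0), 1)
        y[i] <- cl - 1L
      }
    }
    image_dataset(X, y, image_shape, split = tag)
  }
  with_seed(seed, {
    train <- draw_split(train_per_class, "train")
    test <- draw_split(test_per_class, "test")
    list(train = train, test = test, centers = centers)
  })
}

#' Stratified train/validation split
#'
#' Seeded stratified split keeping per-class proportions (the 90/10 protocol
#' by default); disjoint and exhaustive. If any class is too small to
#' contribute at least one validation sample, falls back to an unstratified
#' split with a warning.
#'
#' @param data An [image_dataset()] or `list(X, y)`.
#' @param val_fraction Fraction held out, in (0, 1). Default 0.1.
#' @param seed Integer seed.
#' @return List with `train` and `val` (same structure as the input, as
#'   `list(X, y)`).
#' @export
train_val_split <- function(data, val_fraction = 0.1, seed = 1L) {
  val_fraction <- assert_fraction(val_fraction, "val_fraction")
  data <- as_xy(data)
  n <- nrow(data$X)
  classes <- unique(data$y)
  per_class_val <- vapply(classes, function(cl) {
    round(sum(data$y == cl) * val_fraction)
  }, numeric(1))
  val_idx <- with_seed(seed, {
    if (any(per_class_val < 1)) {
      warning("a class is too small for a stratified split; ",
              "falling back to an unstratified split", call. = FALSE)
      sample.int(n, max(1L, round(n * val_fraction)))
    } else {
      unlist(lapply(seq_along(classes), function(j) {
        members <- which(data$y == classes[j])
        sample(members, per_class_val[j])
      }))
    }
  })
  val_idx <- sort(val_idx)
  tr_idx <- setdiff(seq_len(n), val_idx)
  list(train = list(X = data$X[tr_idx, , drop = FALSE], y = data$y[tr_idx]),
       val = list(X = data$X[val_idx, , drop = FALSE], y = data$y[val_idx]))
}
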