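# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, fixed RNG state
#'
#' Runs `expr` with the random number generator seeded to `seed` using fixed
#' generator kinds (Mersenne-Twister / Inversion / Rejection), then restores
#' whatever RNG state existed before the call. All stochastic constructors in
#' the package route their randomness through this helper so that results are
#' pure functions of their arguments and seed, with no hidden global state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# argument checking -----------------------------------------------------------

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_fraction <- function(x, name, open_lower = TRUE, open_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lower) x > 0 else x >= 0) &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) stop(sprintf("`%s` must be a fraction in the valid range", name), call. = FALSE)
  as.numeric(x)
}

assert_finite_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

# Feature index of an (row, col, channel) pixel under the package-wide
# flattening convention: row-major, channel-last.
# index = ((r - 1) * w + (c - 1)) * ch + k, 1-based.
pixel_index <- function(row, col, channel, image_shape) {
  h <- image_shape[1L]; w <- image_shape[2L]; ch <- image_shape[3L]
  ((row - 1L) * w + (col - 1L)) * ch + channel
}

n_features_of <- function(image_shape) {
  as.integer(prod(image_shape))
}

normalize_image_shape <- function(image_shape) {
  if (length(image_shape) == 2L) image_shape <- c(image_shape, 1L)
  if (length(image_shape) != 3L || any(image_shape < 1L)) {
    stop("`image_shape` must be (height, width) or (height, width, channels)",
         call. = FALSE)
  }
  as.integer(image_shape)
}
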