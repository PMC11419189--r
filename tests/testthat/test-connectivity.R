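test_that("structure mask wires each dendrite to exactly one soma in blocks", {
  m <- build_structure_mask(2, 3)
  expect_equal(dim(m), c(6L, 2L))
  expect_true(all(m[1:3, 1]) && all(m[4:6, 2]))
  expect_false(any(m[1:3, 2]) || any(m[4:6, 1]))

  expect_equal(build_structure_mask(1, 1), matrix(TRUE, 1, 1))

  m <- build_structure_mask(4, 8)
  expect_equal(colSums(m), rep(8, 4))
  expect_equal(rowSums(m), rep(1, 32))

  # randomized grid: row sums 1, column sums D, always
  set.seed(7)
  for (i in 1:10) {
    S <- sample(1:12, 1); D <- sample(1:12, 1)
    m <- build_structure_mask(S, D)
    expect_equal(rowSums(m), rep(1, S * D))
    expect_equal(colSums(m), rep(D, S))
  }

  expect_error(build_structure_mask(0, 3), "n_somata")
  expect_error(build_structure_mask(3, -1), "dendrites_per_soma")
})

test_that("random input sampling draws the right number of distinct pixels", {
  m <- sample_random_inputs(c(28, 28), 10, rf_spec(), seed = 5)
  expect_equal(dim(m), c(784L, 10L))
  expect_equal(colSums(m), rep(16, 10))

  # forced saturation: 16 pixels, 16 synapses
  m1 <- sample_random_inputs(c(4, 4), 1, rf_spec(), seed = 1)
  expect_true(all(m1))

  expect_error(sample_random_inputs(c(3, 3), 1, rf_spec()),
               "synapses_per_dendrite")
})

test_that("mask construction is a pure function of arguments and seed", {
  for (i in 1:100) {
    a <- sample_random_inputs(c(8, 8), 3, rf_spec(window_shape = c(8, 8)), seed = i)
    b <- sample_random_inputs(c(8, 8), 3, rf_spec(window_shape = c(8, 8)), seed = i)
    expect_identical(a, b)
    d <- sample_random_inputs(c(8, 8), 3, rf_spec(window_shape = c(8, 8)), seed = i + 1000L)
    expect_true(any(a != d))
  }
  expect_identical(sample_lrf(c(28, 28), 7, seed = 3),
                   sample_lrf(c(28, 28), 7, seed = 3))
  expect_identical(sample_grf(c(28, 28), 3, 4, seed = 3),
                   sample_grf(c(28, 28), 3, 4, seed = 3))
  expect_identical(random_sparse_masks(c(28, 28), 16, 4, 0.1, 0.5, seed = 9),
                   random_sparse_masks(c(28, 28), 16, 4, 0.1, 0.5, seed = 9))
})

test_that("LRF windows are contiguous in-image 4x4 patches", {
  m <- sample_lrf(c(28, 28), 50, seed = 11)
  expect_equal(colSums(m), rep(16, 50))
  for (d in seq_len(ncol(m))) {
    feat <- which(m[, d]) - 1L
    rows <- feat %/% 28L; cols <- feat %% 28L
    expect_equal(sort(unique(rows)), min(rows) + 0:3)
    expect_equal(sort(unique(cols)), min(cols) + 0:3)
    expect_true(min(rows) >= 0 && max(rows) <= 27)
    expect_true(min(cols) >= 0 && max(cols) <= 27)
  }

  # only one valid anchor on a 4x4 image
  m1 <- sample_lrf(c(4, 4), 1, seed = 1)
  expect_true(all(m1))

  expect_error(sample_lrf(c(3, 10), 1, rf_spec()), "larger than the image")
})

test_that("LRF anchors are uniform over the valid anchor grid", {
  n_dend <- 10000L
  m <- sample_lrf(c(28, 28), n_dend, seed = 99)
  anchors <- vapply(seq_len(n_dend), function(d) {
    feat <- which(m[, d]) - 1L
    c(min(feat %/% 28L), min(feat %% 28L))
  }, numeric(2))
  # 25 x 25 valid anchors; chi-square GOF against the uniform law
  cell <- anchors[1, ] * 25 + anchors[2, ] + 1
  obs <- tabulate(cell, nbins = 625L)
  p <- stats::chisq.test(obs, p = rep(1 / 625, 625))$p.value
  expect_gt(p, 0.01)
})

test_that("GRF dendrites cluster around their soma's receptive-field center", {
  # zero spread: all dendrites of a soma share one window
  m0 <- sample_grf(c(28, 28), 3, 5, rf_spec(grf_spread = 0), seed = 2)
  for (s in 1:3) {
    cols <- (s - 1) * 5 + 1:5
    expect_true(all(m0[, cols] == m0[, cols[1]]))
  }

  anchor_of <- function(m, d) {
    feat <- which(m[, d]) - 1L
    c(min(feat %/% 28L), min(feat %% 28L))
  }
  # window centers within Chebyshev distance grf_spread of the soma center
  # (after clipping, anchors can only move toward the interior)
  spread <- 2
  within_disp <- numeric(0); between_disp <- numeric(0)
  for (seed in 1:50) {
    m <- sample_grf(c(28, 28), 2, 4, rf_spec(grf_spread = spread), seed = seed)
    a <- vapply(1:8, anchor_of, numeric(2), m = m)
    for (s in 1:2) {
      blk <- a[, (s - 1) * 4 + 1:4]
      ctr <- rowMeans(blk)
      expect_true(all(abs(blk - ctr) <= 2 * spread))
      within_disp <- c(within_disp,
                       mean(sqrt(colSums((blk - ctr)^2))))
    }
    between_disp <- c(between_disp,
                      sqrt(sum((rowMeans(a[, 1:4]) - rowMeans(a[, 5:8]))^2)))
  }
  expect_lt(mean(within_disp), mean(between_disp))
})

test_that("sparse random masks match a reference dANN's nonzero counts", {
  ref <- dann_masks("R", c(28, 28), n_somata = 10, dendrites_per_soma = 8,
                    seed = 4)
  expect_equal(sum(ref$input_mask), 1280)
  expect_equal(sum(ref$structure_mask), 80)
  dens <- matched_densities(ref)
  s <- random_sparse_masks(c(28, 28), 80, 10, dens[1], dens[2], seed = 5)
  expect_equal(sum(s$input_mask), 1280)
  expect_equal(sum(s$structure_mask), 80)

  # density 1 in both layers is fully connected wiring, identical to vANN
  full <- random_sparse_masks(c(28, 28), 6, 3, 1, 1, seed = 1)
  expect_true(all(full$input_mask) && all(full$structure_mask))

  expect_error(random_sparse_masks(c(28, 28), 6, 3, 0, 0.5), "densities")
  expect_error(random_sparse_masks(c(28, 28), 6, 3, 0.5, 1.2), "densities")
})

test_that("input mask column sums hold over a randomized grid of shapes", {
  set.seed(31)
  for (i in 1:15) {
    h <- sample(8:30, 1); w <- sample(8:30, 1)
    nd <- sample(1:40, 1)
    k <- sample(1:16, 1)
    win <- c(sample(2:4, 1), sample(2:4, 1))
    k_win <- min(k, prod(win))
    sp <- rf_spec(window_shape = win, synapses_per_dendrite = k_win)
    expect_equal(colSums(sample_random_inputs(c(h, w), nd, sp, seed = i)),
                 rep(k_win, nd))
    expect_equal(colSums(sample_lrf(c(h, w), nd, sp, seed = i)),
                 rep(k_win, nd))
    expect_equal(colSums(sample_grf(c(h, w), nd, 1, sp, seed = i)),
                 rep(k_win, nd))
  }
})

test_that("multi-channel sampling takes all channels of a drawn location", {
  sp <- rf_spec(synapses_per_dendrite = 16)
  m <- sample_lrf(c(28, 28, 3), 5, sp, seed = 1)
  expect_equal(colSums(m), rep(48, 5))  # 16 locations x 3 channels
  mr <- sample_random_inputs(c(28, 28, 3), 5, sp, seed = 1)
  expect_equal(colSums(mr), rep(48, 5))
})

test_that("mask archives round-trip bit-exactly", {
  mp <- dann_masks("GRF", c(16, 16), 4, 4, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  write_masks(mp, path)
  expect_identical(read_masks(path), mp)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(read_masks(bad), "not a mask archive")
})
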