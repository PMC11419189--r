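test_that("silhouette matches closed forms, the oracle, and cluster::silhouette", {
  # coincident-point clusters at distance 10: a = 0, s = 1
  coords <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  labels <- rep(0:1, each = 5)
  expect_equal(silhouette_score(coords, labels), 1)

  # 4 points on a line, hand computation
  line <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(0, 0, 1, 1)
  s0 <- (10.5 - 1) / 10.5; s1 <- (9.5 - 1) / 9.5
  expect_equal(silhouette_score(line, lab), mean(c(s0, s1, s1, s0)),
               tolerance = 1e-12)

  # random labels on one blob: near zero
  set.seed(3)
  blob <- matrix(rnorm(500 * 2), 500)
  rand_lab <- sample(0:1, 500, replace = TRUE)
  expect_lt(abs(silhouette_score(blob, rand_lab)), 0.05)

  # oracle and library agreement on random instances
  for (i in 1:30) {
    set.seed(i)
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * 3), n)
    y <- sample(0:2, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    mine <- silhouette_score(x, y)
    expect_equal(mine, silhouette_oracle(x, y), tolerance = 1e-12)
    if (all(table(y) >= 2)) {
      lib <- mean(cluster::silhouette(y, stats::dist(x))[, "sil_width"])
      expect_equal(mine, lib, tolerance = 1e-10)
    }
  }

  expect_error(silhouette_score(blob, rep(0, 500)), "2 classes")
  expect_equal(silhouette_score(rbind(c(0, 0), c(5, 5), c(6, 6)),
                                c(0, 1, 1), singleton = "zero"),
               mean(c(0, (sqrt(50) - sqrt(2)) / sqrt(50),
                      (sqrt(72) - sqrt(2)) / sqrt(72))))
  expect_error(silhouette_score(rbind(c(0, 0), c(5, 5), c(6, 6)),
                                c(0, 1, 1), singleton = "error"), "single")
})

test_that("neighborhood hit matches hand-enumerated and simulated baselines", {
  # two tight same-class pairs far apart, k = 1
  coords <- rbind(c(0, 0), c(0, 0.1), c(100, 0), c(100, 0.1))
  expect_equal(neighborhood_hit(coords, c(0, 0, 1, 1), k = 1), 1)

  # alternating labels on a line, k = 1: every nearest neighbor differs
  line <- matrix(c(0, 1, 1.9, 3), ncol = 1)
  expect_equal(neighborhood_hit(line, c(0, 1, 0, 1), k = 1), 0)

  # random labels approach the class-proportion baseline
  set.seed(10)
  n <- 1000
  x <- matrix(rnorm(n * 2), n)
  y <- sample(0:9, n, replace = TRUE)
  expect_lt(abs(neighborhood_hit(x, y, k = 11) - 0.1), 0.03)

  # oracle agreement
  for (i in 1:30) {
    set.seed(100 + i)
    n <- sample(20:60, 1)
    x <- matrix(rnorm(n * 2), n)
    y <- sample(0:3, n, replace = TRUE)
    k <- sample(1:11, 1)
    expect_equal(neighborhood_hit(x, y, k), nh_oracle(x, y, k),
                 tolerance = 1e-12)
  }

  expect_error(neighborhood_hit(line, c(0, 1, 0, 1), k = 4), "smaller")
})

test_that("trustworthiness is 1 for identity projections and matches the oracle", {
  set.seed(17)
  x <- matrix(rnorm(60 * 5), 60)
  expect_equal(trustworthiness(x, x, k = 11), 1)

  # order-reversing projection of a line of distinct points
  n <- 50
  line <- matrix(seq_len(n) + cumsum(runif(n, 0.01, 0.2)), ncol = 1)
  reversed <- -line
  # rank structure is preserved under reversal of a 1-D set, so T = 1;
  # a random shuffle of the same points is not trustworthy
  expect_equal(trustworthiness(line, reversed, k = 5),
               trustworthiness_oracle(line, reversed, 5), tolerance = 1e-12)
  shuffled <- matrix(sample(line), ncol = 1)
  expect_equal(trustworthiness(line, shuffled, k = 5),
               trustworthiness_oracle(line, shuffled, 5), tolerance = 1e-12)
  expect_lt(trustworthiness(line, shuffled, k = 5), 1)

  # random projections of a Gaussian cloud: in [0,1] and oracle-equal
  for (i in 1:20) {
    set.seed(200 + i)
    n <- sample(30:80, 1)
    high <- matrix(rnorm(n * 10), n)
    low <- high %*% matrix(rnorm(10 * 2), 10)
    k <- sample(c(3, 5, 11), 1)
    t_pkg <- trustworthiness(high, low, k)
    expect_equal(t_pkg, trustworthiness_oracle(high, low, k),
                 tolerance = 1e-12)
    expect_gte(t_pkg, 0); expect_lte(t_pkg, 1)
  }

  expect_error(trustworthiness(x[1:5, ], x[1:5, 1:2], k = 3), "degenerate")
  expect_error(trustworthiness(x, x[1:10, ], k = 3), "same number of rows")
})

test_that("scores are invariant under rigid motions of the embedding", {
  set.seed(23)
  n <- 80
  coords <- matrix(rnorm(n * 2), n)
  y <- sample(0:3, n, replace = TRUE)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- coords %*% rot + matrix(c(5, -3), n, 2, byrow = TRUE)
  expect_equal(silhouette_score(moved, y), silhouette_score(coords, y),
               tolerance = 1e-9)
  expect_equal(neighborhood_hit(moved, y, 7), neighborhood_hit(coords, y, 7),
               tolerance = 1e-12)
  high <- matrix(rnorm(n * 6), n)
  expect_equal(trustworthiness(high, moved, 7),
               trustworthiness(high, coords, 7), tolerance = 1e-12)
})

test_that("t-SNE embedding separates well-separated blobs and is seeded", {
  centers <- matrix(0, 2, 50)
  centers[2, ] <- 10   # two isotropic blobs 10 sd apart in 50-D
  d <- make_blobs(100, centers, sd = 1, seed = 5)

  run <- embed_activations(d$X, d$y, subset_size = 200, perplexity = 30,
                           seed = 1, max_iter = 500)
  expect_equal(dim(run$coords), c(200L, 2L))
  expect_true(all(is.finite(run$coords)))

  # identical subset selection for the same seed
  run2 <- embed_activations(d$X, d$y, subset_size = 150, perplexity = 30,
                            seed = 4, max_iter = 250)
  run3 <- embed_activations(d$X, d$y, subset_size = 150, perplexity = 30,
                            seed = 4, max_iter = 250)
  expect_identical(run2$indices, run3$indices)
  expect_equal(run2$coords, run3$coords)

  # silhouette above 0.5 across 10 seeds
  sils <- vapply(1:10, function(s) {
    r <- embed_activations(d$X, d$y, subset_size = 150, perplexity = 25,
                           seed = s, max_iter = 400)
    silhouette_score(r$coords, r$labels)
  }, numeric(1))
  expect_true(all(sils > 0.5))

  # no subsampling when subset_size = n
  run_all <- embed_activations(d$X[1:80, ], d$y[1:80], subset_size = 80,
                               perplexity = 10, seed = 2, max_iter = 250)
  expect_equal(sort(run_all$indices), 1:80)

  expect_error(embed_activations(d$X, d$y, subset_size = 100,
                                 perplexity = 100, seed = 1), "perplexity")
})
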