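test_that("VCA recovers simplex vertices under the pure-pixel assumption", {
  fx <- simplex_fixture(n = 3)
  est <- vca(fx$d, 3, seed = 2)
  m <- match_endmembers(est, fx$truth)
  expect_lt(m$mean_sad, 1e-6)
  # selected rows are the vertex rows (first three of the fixture)
  expect_setequal(attr(est, "indices"), 1:3)

  # n = 1 degenerate case returns a single data row maximizing the criterion
  est1 <- vca(fx$d, 1, seed = 2)
  expect_identical(nrow(est1$signatures), 1L)
  expect_true(attr(est1, "indices") %in% seq_len(nrow(fx$d$intensities)))

  expect_error(vca(spectral_dataset(matrix(1, 2, 5)), 3),
               class = "ramanmix_error_data")
})

test_that("N-FINDR recovers vertices and its volume trace is monotone", {
  fx <- simplex_fixture(n = 4, b = 30, n_mix = 60, seed = 8)
  est <- nfindr(fx$d, 4, seed = 5)
  m <- match_endmembers(est, fx$truth)
  expect_lt(m$mean_sad, 1e-6)
  tr <- attr(est, "volume_trace")
  expect_true(all(diff(tr) > 0))
  expect_error(nfindr(spectral_dataset(matrix(1, 2, 5)), 3),
               class = "ramanmix_error_data")
})

test_that("N-FINDR matches exhaustive search on 2-endmember instances", {
  set.seed(30)
  for (trial in 1:5) {
    X <- matrix(runif(20 * 6), 20, 6)
    d <- spectral_dataset(X)
    est <- nfindr(d, 2, seed = trial)
    # brute force over all C(20, 2) pairs in the same reduced space
    Z <- prcomp(X, center = TRUE, rank. = 1)$x[, 1]
    pairs <- t(combn(20, 2))
    vols <- abs(Z[pairs[, 1]] - Z[pairs[, 2]])
    best <- pairs[which.max(vols), ]
    expect_setequal(attr(est, "indices"), best)
  }
})

test_that("extractors are deterministic under their seed", {
  fx <- simplex_fixture(n = 3, seed = 12)
  expect_identical(vca(fx$d, 3, seed = 9)$signatures,
                   vca(fx$d, 3, seed = 9)$signatures)
  expect_identical(nfindr(fx$d, 3, seed = 9)$signatures,
                   nfindr(fx$d, 3, seed = 9)$signatures)
})

test_that("NNLS abundances solve the nonnegative least-squares problem", {
  set.seed(31)
  M <- endmember_set(matrix(runif(3 * 10) + 0.2, 3, 10))
  # exact representations
  A1 <- nnls_abundance(M, spectral_dataset(M$signatures[1, , drop = FALSE]))
  expect_equal(A1$values[1, ], c(1, 0, 0), tolerance = 1e-8)
  A0 <- nnls_abundance(M, spectral_dataset(matrix(0, 1, 10)))
  expect_equal(A0$values[1, ], c(0, 0, 0))
  # optimality: objective no worse than any candidate on a dense grid
  x <- runif(10)
  a_hat <- nnls_abundance(M, spectral_dataset(matrix(x, 1)))$values[1, ]
  obj <- function(a) sum((crossprod(M$signatures, a) - x)^2)
  g <- seq(0, 1, by = 0.05)
  grid <- as.matrix(expand.grid(g, g, g))
  grid_best <- min(apply(grid, 1, obj))
  expect_lte(obj(a_hat), grid_best + 1e-9)
  # an on-grid exact instance is matched to 1e-6
  a_true <- c(0.25, 0.5, 0)
  x2 <- drop(crossprod(M$signatures, a_true))
  a2 <- nnls_abundance(M, spectral_dataset(matrix(x2, 1)))$values[1, ]
  expect_lt(sum((drop(crossprod(M$signatures, a2)) - x2)^2), 1e-12)
})

test_that("FCLS abundances satisfy ANC + ASC and recover interior points", {
  set.seed(32)
  M <- endmember_set(matrix(runif(2 * 12) + 0.2, 2, 12))
  x <- 0.3 * M$signatures[1, ] + 0.7 * M$signatures[2, ]
  A <- fcls_abundance(M, spectral_dataset(matrix(x, 1)))
  expect_equal(A$values[1, ], c(0.3, 0.7), tolerance = 1e-6)
  # pure pixel -> one-hot
  A1 <- fcls_abundance(M, spectral_dataset(M$signatures[1, , drop = FALSE]))
  expect_equal(A1$values[1, ], c(1, 0), tolerance = 1e-6)
  # every row sums to one and is nonnegative on arbitrary data
  X <- matrix(runif(20 * 12), 20, 12)
  Aall <- fcls_abundance(M, spectral_dataset(X))
  expect_true(all(Aall$values >= 0))
  expect_lt(max(abs(rowSums(Aall$values) - 1)), 1e-6)
})

test_that("both extractors achieve near-zero SAD on ideal chessboard data", {
  sim <- tiny_chessboard(seed = 33, b = 60, H = 10, W = 10, patch = 5, n = 4)
  for (fn in list(vca, nfindr)) {
    est <- fn(sim$dataset, 4, seed = 1)
    expect_lt(match_endmembers(est, sim$record$endmembers)$mean_sad, 1e-6)
  }
})
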