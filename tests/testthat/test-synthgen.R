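test_that("endmember peak counts follow the stated discrete-uniform laws", {
  set.seed(10)
  clean <- sample_endmembers(50, endmember_params(b = 120))
  expect_true(all(attr(clean, "npeaks") >= 5 & attr(clean, "npeaks") <= 9))
  expect_true(all(attr(clean, "nsmall") == 0))

  noisy <- sample_endmembers(20, endmember_params(b = 120, noisy = TRUE))
  expect_true(all(attr(noisy, "nsmall") >= 50 & attr(noisy, "nsmall") <= 99))
  expect_true(all(noisy$signatures >= 0))
})

test_that("per-peak draws follow the stated height, center and width laws", {
  set.seed(11)
  # ~1,500 endmembers give >= 10,000 major-peak h1 draws
  M <- sample_endmembers(1500, endmember_params(b = 60))
  pk <- attr(M, "peaks")
  h1 <- pk[pk[, "kind"] == 1, "h1"]
  expect_gt(length(h1), 7000)
  # E[h1] = 1 + 5 * E[Beta(1,3)] = 1 + 5/4; sd(h1) = 5 * sd(Beta(1,3))
  se <- 5 * sqrt(3 / (16 * 5)) / sqrt(length(h1))
  expect_lt(abs(mean(h1) - 2.25), 3 * se)
  expect_true(all(h1 > 1 & h1 < 6))
  expect_true(all(pk[, "h2"] >= 0.1 & pk[, "h2"] <= 1))
  expect_true(all(pk[, "center"] >= 10 & pk[, "center"] <= 50))
  expect_true(all(pk[, "sigma"] >= 0.1 & pk[, "sigma"] <= 1))

  set.seed(12)
  Mn <- sample_endmembers(30, endmember_params(b = 60, noisy = TRUE))
  pkn <- attr(Mn, "peaks")
  small <- pkn[pkn[, "kind"] == 2, , drop = FALSE]
  expect_true(all(small[, "h1"] == 1 / 3))
  # small peaks: sigma = 2 * U(0.1, 1)
  expect_true(all(small[, "sigma"] >= 0.2 & small[, "sigma"] <= 2))
})

test_that("major-peak counts are uniform on {5..9}", {
  set.seed(13)
  M <- sample_endmembers(5000, endmember_params(b = 25))
  counts <- table(factor(attr(M, "npeaks"), levels = 5:9))
  se <- sqrt(0.2 * 0.8 / 5000)
  expect_true(all(abs(counts / 5000 - 0.2) < 3 * se))
})

test_that("chessboard scenes are constant one-hot patches", {
  set.seed(2)
  A <- make_scene(scene_params("chessboard", H = 100, W = 100, patch = 20), n = 5)
  V <- A$values
  expect_true(all(V %in% c(0, 1)))
  expect_true(all(rowSums(V) == 1))
  lab <- max.col(V)
  grid <- matrix(lab, 100, 100, byrow = TRUE)
  for (pr in 0:4) for (pc in 0:4) {
    blk <- grid[pr * 20 + 1:20, pc * 20 + 1:20]
    expect_length(unique(as.vector(blk)), 1)
  }
})

test_that("all scene kinds satisfy ANC and ASC exactly", {
  set.seed(3)
  for (kind in c("chessboard", "gaussian", "dirichlet")) {
    A <- make_scene(scene_params(kind, H = 20, W = 20, patch = 5), n = 4)
    expect_true(all(A$values >= 0))
    expect_lt(max(abs(rowSums(A$values) - 1)), 1e-12)
  }
  expect_error(make_scene(scene_params("chessboard", H = 10, W = 10, patch = 3)),
               class = "ramanmix_error_param")
})

test_that("symmetric Dirichlet scenes have per-component mean 1/n", {
  set.seed(4)
  A <- make_scene(scene_params("dirichlet", H = 100, W = 100), n = 5)
  # Dirichlet(1,...,1): mean 1/5, var (1/5)(4/5)/6
  se <- sqrt(0.2 * 0.8 / 6) / sqrt(10000)
  expect_true(all(abs(colMeans(A$values) - 0.2) < 3 * se))
})

test_that("linear and Fan mixing match hand-computed cases", {
  M <- endmember_set(rbind(m1 = c(1, 2, 3), m2 = c(4, 5, 6)))
  # one-hot abundance kills all Fan cross terms
  one_hot <- abundance_map(c(1, 0))
  expect_equal(mix_spectra(M, one_hot, "fan")$intensities[1, ], c(1, 2, 3))
  # alpha = (0.5, 0.5): x = 0.5 m1 + 0.5 m2 + 2 * (0.25 m1 .* m2)
  half <- abundance_map(c(0.5, 0.5))
  expected <- 0.5 * c(1, 2, 3) + 0.5 * c(4, 5, 6) + 0.5 * c(1, 2, 3) * c(4, 5, 6)
  expect_equal(mix_spectra(M, half, "fan")$intensities[1, ], expected)
  expect_equal(mix_spectra(M, half, "linear")$intensities[1, ],
               0.5 * c(1, 2, 3) + 0.5 * c(4, 5, 6))
  # chessboard + linear: every spectrum equals a ground-truth endmember
  sim <- tiny_chessboard(seed = 5)
  X <- sim$dataset$intensities
  Mt <- sim$record$endmembers$signatures
  k <- max.col(sim$record$abundances$values)
  expect_identical(X, unname(Mt[k, , drop = FALSE]))
  expect_error(mix_spectra(M, abundance_map(c(1, 0, 0) / 1)),
               class = "ramanmix_error_dim")
})

test_that("artifact injection matches its closed forms and flags", {
  d0 <- spectral_dataset(matrix(0, 5, 200))
  set.seed(6)
  onlyB <- add_artifacts(d0, artifact_params(sigma_noise = 0, p_baseline = 1,
                                             p_spike = 0))
  # baseline at band j is hB * atan(pi * j / b); at j = b it is 2 * atan(pi)
  expect_equal(onlyB$intensities[3, 200], 2 * atan(pi), tolerance = 1e-12)
  expect_equal(onlyB$intensities[1, 50], 2 * atan(pi * 50 / 200),
               tolerance = 1e-12)
  expect_true(all(attr(onlyB, "flags")$baseline_added))

  set.seed(7)
  noop <- add_artifacts(d0, artifact_params(sigma_noise = 0, p_baseline = 0,
                                            p_spike = 0))
  expect_identical(noop$intensities, d0$intensities)

  set.seed(8)
  big <- spectral_dataset(matrix(0, 4000, 64))
  sp <- add_artifacts(big, artifact_params(sigma_noise = 0, p_baseline = 0,
                                           p_spike = 1))
  fl <- attr(sp, "flags")
  expect_true(all(fl$spike_added))
  expect_true(all(fl$spike_band >= 2 & fl$spike_band <= 62))
  expect_true(all(fl$spike_height >= 5 * 0.75 & fl$spike_height <= 5 * 1.25))
  hit <- sp$intensities[cbind(seq_len(4000), fl$spike_band)]
  expect_equal(hit, fl$spike_height)
})

test_that("generation is deterministic under the seed and composes exactly", {
  a <- generate_raman_dataset("gaussian", "realistic", b = 80, seed = 42,
                              scene_dims = c(8, 8))
  b_ <- generate_raman_dataset("gaussian", "realistic", b = 80, seed = 42,
                               scene_dims = c(8, 8))
  expect_identical(a$dataset$intensities, b_$dataset$intensities)
  expect_identical(a$record$flags, b_$record$flags)

  # ideal scenario: dataset is exactly mix(ground truth)
  sim <- tiny_chessboard(seed = 9)
  rec <- mix_spectra(sim$record$endmembers, sim$record$abundances, "linear")
  expect_identical(rec$intensities, sim$dataset$intensities)

  expect_error(generate_raman_dataset("chessboard", "bilinear", b = 80, seed = 1),
               class = "ramanmix_error_param")
})
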