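test_that("endmember matching handles identity, permutations and surpluses", {
  set.seed(50)
  M <- endmember_set(matrix(runif(5 * 40) + 0.1, 5, 40))
  same <- match_endmembers(M, M)
  expect_identical(same$permutation, 1:5)
  expect_lt(same$total_sad, 1e-6)

  swapped <- endmember_set(M$signatures[c(2, 1, 3, 4, 5), ])
  m2 <- match_endmembers(swapped, M)
  expect_identical(m2$permutation, c(2L, 1L, 3L, 4L, 5L))
  expect_lt(m2$total_sad, 1e-6)

  expect_error(match_endmembers(endmember_set(M$signatures[1:3, ]), M),
               class = "ramanmix_error_param")
})

test_that("Hungarian matching equals brute force up to n_true = 6", {
  set.seed(51)
  for (trial in 1:10) {
    n_true <- sample(2:6, 1)
    n_est <- n_true + sample(0:2, 1)
    truth <- endmember_set(matrix(runif(n_true * 25) + 0.05, n_true, 25))
    est <- endmember_set(matrix(runif(n_est * 25) + 0.05, n_est, 25))
    m <- match_endmembers(est, truth)
    cost <- outer(seq_len(n_true), seq_len(n_est), Vectorize(function(i, j) {
      sad(truth$signatures[i, ], est$signatures[j, ])
    }))
    bf <- brute_force_assignment(cost)
    expect_equal(m$total_sad, bf$value, tolerance = 1e-12)
  }
})

test_that("abundance MSE follows its definition and the matched permutation", {
  expect_equal(abundance_mse(rbind(c(1, 0, 0, 0, 0)), rbind(c(0, 1, 0, 0, 0))),
               0.4, ignore_attr = TRUE)
  expect_equal(abundance_mse(matrix(0, 2, 5), matrix(1, 2, 5)), 1,
               ignore_attr = TRUE)
  expect_equal(abundance_mse(rbind(c(0.2, 0.8)), rbind(c(0.2, 0.8))), 0,
               ignore_attr = TRUE)
  # permuting estimate columns together with the matching leaves MSE unchanged
  set.seed(52)
  A_true <- matrix(runif(10 * 4), 10, 4); A_true <- A_true / rowSums(A_true)
  M_true <- endmember_set(matrix(runif(4 * 30) + 0.1, 4, 30))
  perm <- sample(4)
  est_M <- endmember_set(M_true$signatures[perm, ])
  est_A <- A_true[, perm]
  m <- match_endmembers(est_M, M_true)
  expect_equal(as.numeric(abundance_mse(A_true, est_A, m$permutation)), 0)
})

test_that("matched SAD is invariant to permuting the estimated endmembers", {
  set.seed(53)
  truth <- endmember_set(matrix(runif(4 * 20) + 0.1, 4, 20))
  est <- endmember_set(matrix(runif(6 * 20) + 0.1, 6, 20))
  m1 <- match_endmembers(est, truth)
  shuf <- sample(6)
  m2 <- match_endmembers(endmember_set(est$signatures[shuf, ]), truth)
  expect_equal(m1$total_sad, m2$total_sad, tolerance = 1e-12)
  expect_length(m1$unmatched, 2)
})

test_that("the benchmark grid emits one row per cell and is seed-deterministic", {
  grid <- benchmark_grid(scale = "reduced", scene_dims = c(10, 10), b = 50,
                         dataset_seeds = 1, model_seeds = 1:2, epochs = 1,
                         methods = c("vca", "dense"))
  res <- run_benchmark(grid)
  # 11 variants x 2 methods x 1 dataset seed x 2 model seeds
  expect_identical(nrow(res), 44L)
  expect_setequal(unique(res$method), c("vca_fcls", "dense"))
  expect_true(all(is.na(res$error)))
  expect_true(all(res$mean_sad >= 0))
  # the bilinear scenario never runs on the chessboard scene
  expect_false(any(res$scenario == "bilinear" & res$scene == "chessboard"))
  # ideal chessboard cells: conventional pipeline is numerically exact
  ic <- dplyr::filter(res, scenario == "ideal", scene == "chessboard",
                      method == "vca_fcls")
  expect_true(all(ic$mean_sad <= 1e-6))

  res2 <- run_benchmark(grid)
  expect_identical(res$mean_sad, res2$mean_sad)
  expect_identical(res$abundance_mse, res2$abundance_mse)
})

test_that("runtime profiling emits the requested repetitions per size", {
  prof <- profile_runtime(c(16, 36), methods = c("vca", "dense"),
                          repetitions = 2, b = 30, epochs = 1)
  expect_identical(nrow(prof), 8L)   # 2 sizes x 2 methods x 2 repetitions
  expect_true(all(prof$seconds > 0))
  expect_identical(sort(unique(prof$n_spectra)), c(16L, 36L))
  expect_error(profile_runtime(10), class = "ramanmix_error_param")
})

test_that("the sugar factorial design yields 240 admissible mixtures", {
  des <- sugar_mixture_design()
  expect_identical(nrow(des), 240L)
  expect_true(all(des$total_sugar_volume > 0))
  expect_true(all(des$total_sugar_volume <= 375))
  expect_true(all(des$water_volume >= 0))
  expect_identical(nrow(dplyr::distinct(des)), 240L)
  # without the volume cap and exclusion the full factorial is 4^4
  expect_identical(nrow(sugar_mixture_design(well_volume = Inf)), 255L)
})
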