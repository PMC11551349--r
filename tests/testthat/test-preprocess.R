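test_that("cropping keeps exactly the bands inside the closed window", {
  axis <- seq(142, 3684.8, length.out = 500)
  d <- spectral_dataset(matrix(runif(3 * 500), 3, 500), axis = axis)
  cr <- crop_spectra(d, 400, 1800)
  expect_true(all(cr$axis >= 400 & cr$axis <= 1800))
  expect_identical(ncol(cr$intensities), length(cr$axis))
  # full-range crop is the identity
  full <- crop_spectra(d, min(axis), max(axis))
  expect_identical(full$intensities, d$intensities)
  expect_error(crop_spectra(d, 5000, 6000), class = "ramanmix_error_empty_range")
})

test_that("despiking removes single-band spikes and spares smooth spectra", {
  sm <- smooth_spectrum(200)
  d_smooth <- despike(spectral_dataset(matrix(sm, 1)))
  expect_equal(d_smooth$intensities[1, ], sm, tolerance = 1e-12)

  # flat spectrum with one spiked band returns to the constant level
  y <- rep(2, 100); y[50] <- 9
  fixed <- despike(spectral_dataset(matrix(y, 1)))
  expect_lt(abs(fixed$intensities[1, 50] - 2), 1e-9)

  # a generator cosmic spike (hS = 5) is suppressed below the threshold
  set.seed(40)
  base <- sample_endmembers(1, endmember_params(b = 400, width_multiplier = 8))
  yy <- base$signatures[1, ] + rnorm(400, 0, 0.05)
  yy[123] <- yy[123] + 5
  ds <- despike(spectral_dataset(matrix(yy, 1)))
  mz <- function(v) { dv <- diff(v); 0.6745 * (dv - median(dv)) / median(abs(dv - median(dv))) }
  expect_gt(max(abs(mz(yy))), 8)
  expect_lt(max(abs(mz(ds$intensities[1, ]))), 8)
})

test_that("Savitzky-Golay denoising reproduces cubics and shrinks noise", {
  j <- seq_len(60)
  cub <- 0.002 * j^3 - 0.1 * j^2 + j + 5
  out <- denoise_savgol(spectral_dataset(matrix(cub, 1)))
  expect_equal(out$intensities[1, 4:57], cub[4:57], tolerance = 1e-10)
  # constant spectra pass through
  cst <- denoise_savgol(spectral_dataset(matrix(3, 2, 30)))
  expect_equal(cst$intensities, matrix(3, 2, 30))
  # variance reduction on white noise
  set.seed(41)
  noise <- matrix(rnorm(20 * 300), 20, 300)
  sm <- denoise_savgol(spectral_dataset(noise))
  expect_lt(var(as.vector(sm$intensities)), var(as.vector(noise)))
  expect_error(denoise_savgol(spectral_dataset(matrix(1, 1, 5)), window = 7),
               class = "ramanmix_error_param")
  expect_error(denoise_savgol(spectral_dataset(matrix(1, 1, 50)), window = 6),
               class = "ramanmix_error_param")
})

test_that("asymmetric least squares removes the arctan baseline", {
  b <- 1000
  B <- 2 * atan(pi * seq_len(b) / b)          # generator baseline, hB = 2
  d <- spectral_dataset(matrix(B, 1))
  for (method in c("asls", "aspls")) {
    corr <- baseline_correct(d, method)
    expect_lt(max(abs(corr$intensities)), 0.05 * 2)
  }
  # zero spectra stay zero
  z <- baseline_correct(spectral_dataset(matrix(0, 2, 100)), "asls")
  expect_equal(z$intensities, matrix(0, 2, 100))
  # peak positions survive baseline removal
  j <- seq_len(b)
  x <- numeric(b)
  for (c0 in c(200, 500, 800)) x <- x + 3 * exp(-(j - c0)^2 / 32)
  pk <- baseline_correct(spectral_dataset(matrix(x + B, 1)), "asls")
  for (c0 in c(200L, 500L, 800L)) {
    reg <- (c0 - 40L):(c0 + 40L)
    expect_identical(reg[which.max(pk$intensities[1, reg])], c0)
  }
  expect_error(baseline_correct(d, "asls", lambda = -1),
               class = "ramanmix_error_param")
  expect_error(baseline_correct(d, "asls", p = 1.5),
               class = "ramanmix_error_param")
})

test_that("global normalizations hit their exact ranges and are idempotent", {
  set.seed(42)
  d <- spectral_dataset(matrix(rnorm(10 * 50, 3, 2), 10, 50))
  mm <- normalize_spectra(d, "global_minmax")
  expect_identical(min(mm$intensities), 0)
  expect_identical(max(mm$intensities), 1)
  mm2 <- normalize_spectra(mm, "global_minmax")
  expect_equal(mm2$intensities, mm$intensities)
  gv <- normalize_spectra(d, "global_vector")
  expect_identical(max(abs(gv$intensities)), 1)
  expect_error(normalize_spectra(spectral_dataset(matrix(2, 3, 4)), "global_minmax"),
               class = "ramanmix_error_degenerate")
})

test_that("the sugar and cell pipeline presets run end to end on generated data", {
  sim <- generate_raman_dataset("gaussian", "realistic", b = 300, seed = 43,
                                scene_dims = c(8, 8),
                                endmember_args = list(width_multiplier = 6))
  d <- sim$dataset
  d$axis <- seq(142, 3684.8, length.out = 300)

  sugar <- apply_pipeline(d, "sugar")
  expect_true(all(sugar$axis >= 400 & sugar$axis <= 1800))
  expect_identical(max(abs(sugar$intensities)), 1)
  expect_length(attr(sugar, "log"), 3)

  cell <- apply_pipeline(d, "cell")
  expect_true(all(cell$axis >= 700 & cell$axis <= 1800))
  expect_identical(range(cell$intensities), c(0, 1))
  expect_length(attr(cell, "log"), 5)
  expect_match(attr(cell, "log")[4], "asls")

  # per-step overrides are honored
  wide <- apply_pipeline(d, "sugar", overrides = list(crop = list(lo = 200)))
  expect_gt(ncol(wide$intensities), ncol(sugar$intensities))

  # shape contracts: every step preserves the spectrum count
  expect_identical(nrow(cell$intensities), nrow(d$intensities))
})
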