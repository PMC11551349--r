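test_that("soft_rectified_tanh matches its closed form and limits", {
  expect_equal(soft_rectified_tanh(0), log(2) / 10, tolerance = 1e-12)
  expect_equal(soft_rectified_tanh(1e6), log1p(exp(10)) / 10, tolerance = 1e-9)
  expect_equal(soft_rectified_tanh(-1e6), log1p(exp(-10)) / 10, tolerance = 1e-12)
  # strictly positive and monotone
  x <- seq(-5, 5, by = 0.01)
  y <- soft_rectified_tanh(x)
  expect_true(all(y > 0))
  expect_true(all(diff(y) > 0))
})

test_that("decoders mirror the generator's mixing models exactly", {
  set.seed(20)
  W <- matrix(runif(30 * 4), 30, 4)
  lin <- decoder_spec("linear", W)
  fan <- decoder_spec("fan", W)
  # one-hot latent reproduces the corresponding column
  expect_equal(decode(c(0, 1, 0, 0), lin), W[, 2])
  expect_equal(decode(c(0, 1, 0, 0), fan), W[, 2])
  expect_equal(decode(numeric(4), fan), numeric(30))
  # duality with mix_spectra at machine precision
  Z <- matrix(runif(12), 3, 4)
  M <- endmember_set(t(W))
  A <- abundance_map(Z, anc = TRUE, asc = FALSE)
  for (kind in c("linear", "fan")) {
    dec <- decoder_spec(kind, W)
    expect_equal(decode(Z, dec),
                 mix_spectra(M, A, model = if (kind == "fan") "fan" else "linear")$intensities,
                 tolerance = 1e-14)
  }
  expect_error(decode(c(1, 2), lin), class = "ramanmix_error_dim")
  expect_error(decoder_spec("linear", matrix(-1, 2, 2)),
               class = "ramanmix_error_param")
})

test_that("sad has the expected values, symmetry and scale invariance", {
  v <- runif(10) + 0.1
  expect_equal(sad(v, v), 0)
  expect_equal(sad(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(sad(c(1, 0), c(1, 1)), pi / 4)
  a <- runif(20); b <- runif(20)
  expect_equal(sad(a, b), sad(b, a))
  expect_equal(sad(a, 17.3 * b), sad(a, b))
  expect_error(sad(numeric(5), a[1:5]), class = "ramanmix_error_domain")
})

test_that("training_loss combines SAD and band-mean MSE as specified", {
  x <- c(1, 0); xh <- c(1, 1)
  expect_equal(training_loss(x, x, "sad"), 0)
  expect_equal(training_loss(x, 2 * x, "sad"), 0)          # scale invariance
  expect_equal(training_loss(x, xh, "sad_mse", lambda = 1000),
               pi / 4 + 1000 * 0.5, tolerance = 1e-12)
  # batch mode averages over rows
  X <- rbind(c(1, 0), c(1, 0)); Xh <- rbind(c(1, 1), c(1, 0))
  expect_equal(training_loss(X, Xh, "sad"), pi / 8)
})

test_that("analytic gradients agree with finite differences", {
  ns <- asNamespace("ramanmix")
  set.seed(21)
  b <- 18; m <- 2; X <- matrix(abs(rnorm(3 * b)), 3, b)
  for (enc in c("dense", "conv", "transformer")) {
    model <- ae_model(b, m,
                      encoder = encoder_spec(enc, b = b, m = m, hidden = c(8),
                                             embed_dim = 4L, head_dim = 3L,
                                             ff_dim = 6L, dropout = 0),
                      decoder = "fan", asc = TRUE)
    set.seed(1)
    params <- ns$init_params(model)
    lossval <- function(pl) {
      nodes <- lapply(pl, ns$ad_const)
      fwd <- ns$ae_forward(model, nodes, X, training = FALSE)
      ns$ad_recon_loss(fwd$xhat, X, lambda = 0.3)$value
    }
    nodes <- lapply(params, ns$ad_param)
    fwd <- ns$ae_forward(model, nodes, X, training = FALSE)
    lo <- ns$ad_recon_loss(fwd$xhat, X, lambda = 0.3)
    ns$ad_backward(lo)
    for (nm in names(params)) {
      g <- nodes[[nm]]$grad
      if (is.null(g)) g <- params[[nm]] * 0
      idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
      for (i in idx) {
        eps <- 1e-6
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        num <- (lossval(p1) - lossval(p2)) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-4), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and preserves all constraints", {
  sim <- tiny_chessboard(seed = 22)
  model <- ae_model(100, 3, encoder = "dense", decoder = "linear", asc = TRUE)
  cfg <- training_config(epochs = 10, seed = 1)
  fit <- fit_autoencoder(model, sim$dataset, cfg)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])
  expect_true(all(fit$min_W_trace >= 0))      # W >= 0 at every checkpoint

  # deterministic given the seed
  fit2 <- fit_autoencoder(model, sim$dataset, cfg)
  expect_identical(fit$loss_trace, fit2$loss_trace)
  expect_identical(fit$params$dec.W, fit2$params$dec.W)

  M <- extract_endmembers(fit)
  expect_true(all(M$signatures >= 0))
  A <- infer_abundances(fit, sim$dataset)
  expect_true(all(A$values >= 0))
  expect_lt(max(abs(rowSums(A$values) - 1)), 1e-6)

  tt <- tidy(fit)
  expect_identical(names(tt), c("epoch", "loss", "min_decoder_weight"))
  expect_identical(nrow(glance(fit)), 1L)
})

test_that("ANC-only models emit abundances in the soft-rectified-tanh range", {
  sim <- tiny_chessboard(seed = 23)
  model <- ae_model(100, 3, encoder = "dense", decoder = "linear", asc = FALSE)
  fit <- fit_autoencoder(model, sim$dataset, training_config(epochs = 3, seed = 2))
  A <- infer_abundances(fit, sim$dataset)
  expect_false(A$asc)
  expect_true(all(A$values > 0))
  expect_true(all(A$values <= log1p(exp(10)) / 10))   # upper limit ~1.0000454
})

test_that("every encoder architecture trains end to end on small data", {
  sim <- tiny_chessboard(seed = 24, b = 40, H = 6, W = 6, patch = 3, n = 2)
  for (enc in c("dense", "deep_dense", "conv", "transformer", "conv_transformer")) {
    fit <- fit_autoencoder(
      ae_model(40, 2, encoder = enc, decoder = "linear", asc = TRUE),
      sim$dataset, training_config(epochs = 2, batch_size = 16, seed = 3))
    expect_true(all(is.finite(fit$loss_trace)))
    A <- infer_abundances(fit, sim$dataset)
    expect_identical(dim(A$values), c(36L, 2L))
  }
})

test_that("nonblind unmixing keeps a fixed decoder exactly at the given endmembers", {
  sim <- tiny_chessboard(seed = 25)
  truth <- sim$record$endmembers
  model <- ae_model(100, 3, encoder = "dense", decoder = "linear", asc = TRUE,
                    decoder_init = truth, decoder_fixed = TRUE)
  fit <- fit_autoencoder(model, sim$dataset, training_config(epochs = 2, seed = 1))
  expect_identical(fit$params$dec.W, t(truth$signatures))
  expect_lt(match_endmembers(extract_endmembers(fit), truth)$total_sad, 1e-6)
})

test_that("untrained model state and dimension mismatches raise typed errors", {
  sim <- tiny_chessboard(seed = 26)
  expect_error(extract_endmembers(list()), class = "ramanmix_error_state")
  expect_error(infer_abundances(42, sim$dataset), class = "ramanmix_error_state")
  model <- ae_model(50, 3)
  expect_error(fit_autoencoder(model, sim$dataset, training_config(epochs = 1)),
               class = "ramanmix_error_dim")
  expect_error(encoder_spec("dense", b = 10, m = 11), class = "ramanmix_error_param")
})
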