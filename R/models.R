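# Physics-constrained unmixing autoencoders: architecture specs, constraint
# activations, losses, the Adam training loop with decoder-weight clipping,
# and extraction of endmembers / abundances from a trained model.

#' Softly rectified hyperbolic tangent
#'
#' The latent activation used to impose the abundance nonnegativity
#' constraint when abundances need not sum to one:
#' `y = (1/gamma) * log(1 + exp(gamma * tanh(x)))` with `gamma = 10` by
#' default. Strictly positive, monotone increasing, and bounded just above
#' 1 (`y(+Inf) = log(1 + e^gamma)/gamma ~ 1.0000454` at `gamma = 10`), so
#' latent codes behave like fractional abundances in `(0, ~1)`.
#'
#' @param x Numeric scalar or array.
#' @param gamma Sharpness parameter, `> 0`.
#' @return Same shape as `x`.
#' @export
#' @examples
#' soft_rectified_tanh(0) # log(2)/10
soft_rectified_tanh <- function(x, gamma = 10) {
  stopifnot(gamma > 0)
  gx <- gamma * tanh(x)
  ifelse(gx > 30, gx + log1p(exp(-gx)), log1p(exp(gx))) / gamma
}

#' Encoder architecture specification
#'
#' @param kind One of `"dense"` (two fully connected layers, hidden width
#'   128, Leaky ReLU slope 0.02), `"deep_dense"` (hidden widths 512, 256,
#'   128, 64, 32), `"conv"` (two parallel 1D convolution banks of 16 filters
#'   of length 3 and 16 of length 5, ReLU, zero padding, channel-merged back
#'   to width `b`, then the dense encoder), `"transformer"` (scalar tokens
#'   embedded to width 32, one transformer block with 2 attention heads of
#'   size 32, feed-forward 64 -> 32, dropout 0.10, layer normalization, then
#'   mean-pooled into the final dense layer), or `"conv_transformer"` (the
#'   convolution banks feeding 32-channel tokens into the transformer
#'   block).
#' @param b Input dimension (bands).
#' @param m Latent dimension (endmembers to learn), `1 <= m <= b`.
#' @param hidden Hidden widths of the dense head (defaults per `kind`).
#' @param leaky_slope Leaky ReLU slope.
#' @param embed_dim,n_heads,head_dim,ff_dim,dropout Transformer block
#'   hyperparameters.
#' @param positional_encoding Add a sinusoidal positional encoding to the
#'   token embeddings (off by default).
#' @return A list of class `encoder_spec`.
#' @export
encoder_spec <- function(kind = c("dense", "deep_dense", "conv",
                                  "transformer", "conv_transformer"),
                         b, m,
                         hidden = NULL, leaky_slope = 0.02,
                         embed_dim = 32L, n_heads = 2L, head_dim = 32L,
                         ff_dim = 64L, dropout = 0.10,
                         positional_encoding = FALSE) {
  kind <- match.arg(kind)
  # the conv banks emit 16 + 16 channels, which are the transformer tokens
  if (kind == "conv_transformer") embed_dim <- 32L
  if (m < 1 || m > b) {
    rmx_abort(sprintf("Latent dim m = %d must be in [1, b = %d].", m, b),
              "ramanmix_error_param")
  }
  hidden <- hidden %||% switch(kind,
    deep_dense = c(512L, 256L, 128L, 64L, 32L),
    c(128L))
  structure(as.list(environment()), class = "encoder_spec")
}

#' Decoder specification
#'
#' A single linear layer with nonnegative `b x m` weight matrix `W`,
#' identity activation and no bias. `"linear"` computes `Wz`; `"fan"` adds
#' the bilinear Fan interaction terms
#' `sum_k sum_{l != k} z_k w_k * z_l w_l` (all ordered pairs), the exact
#' algebraic mirror of [mix_spectra()] with `M = t(W)`.
#'
#' @param kind `"linear"` or `"fan"`.
#' @param W Nonnegative `b x m` weight matrix (columns are endmembers).
#' @return A list of class `decoder_spec`.
#' @export
decoder_spec <- function(kind = c("linear", "fan"), W) {
  kind <- match.arg(kind)
  W <- as.matrix(W)
  if (any(W < 0)) {
    rmx_abort("Decoder weights must be nonnegative.", "ramanmix_error_param")
  }
  structure(list(kind = kind, W = W), class = "decoder_spec")
}

#' Decode latent abundances into spectra
#'
#' Applies the decoder mixing function to one or more latent abundance
#' vectors: `Wz` for the linear decoder, plus all ordered bilinear Fan
#' cross terms for the `"fan"` decoder.
#'
#' @param z Length-`m` vector or `N x m` matrix of latent abundances.
#' @param decoder A [decoder_spec()].
#' @return Length-`b` vector (vector input) or `N x b` matrix.
#' @export
decode <- function(z, decoder) {
  stopifnot(inherits(decoder, "decoder_spec"))
  vec <- is.null(dim(z))
  Z <- if (vec) matrix(z, nrow = 1) else as.matrix(z)
  W <- decoder$W
  if (ncol(Z) != ncol(W)) {
    rmx_abort(sprintf("z has %d components but W has %d columns.",
                      ncol(Z), ncol(W)), "ramanmix_error_dim")
  }
  X <- Z %*% t(W)
  if (decoder$kind == "fan") {
    X <- X + X * X - (Z * Z) %*% t(W * W)
  }
  if (vec) drop(X) else X
}

#' Reconstruction training loss
#'
#' `loss = "sad"`: batch mean of the spectral angle distance between each
#' input spectrum and its reconstruction (scale-invariant).
#' `loss = "sad_mse"`: adds `lambda` times the per-pair mean squared error
#' (mean over bands), breaking the scale invariance; used on high-SNR data
#' where absolute intensity carries information.
#'
#' @param x,xhat Spectra and reconstructions (vectors or `N x b` matrices).
#' @param loss `"sad"` or `"sad_mse"`.
#' @param lambda MSE weight (default 1000).
#' @return Scalar loss.
#' @export
training_loss <- function(x, xhat, loss = c("sad", "sad_mse"), lambda = 1000) {
  loss <- match.arg(loss)
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  Xh <- if (is.null(dim(xhat))) matrix(xhat, nrow = 1) else as.matrix(xhat)
  stopifnot(all(dim(X) == dim(Xh)))
  sads <- vapply(seq_len(nrow(X)), function(i) sad(X[i, ], Xh[i, ]), numeric(1))
  out <- mean(sads)
  if (loss == "sad_mse") out <- out + lambda * mean(rowMeans((Xh - X)^2))
  out
}

#' Training configuration
#'
#' @param epochs Training epochs (the synthetic benchmarks use 10; 15/50
#'   were used for low/high-SNR experimental data and 20 for the cell scan).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 64).
#' @param loss `"sad"` or `"sad_mse"`.
#' @param lambda MSE weight for `"sad_mse"` (default 1000).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param shuffle Reshuffle spectra every epoch.
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 10L, learning_rate = 0.001,
                            batch_size = 64L, loss = c("sad", "sad_mse"),
                            lambda = 1000, seed = 1L, shuffle = TRUE) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, lambda > 0, batch_size >= 1)
  structure(as.list(environment()), class = "training_config")
}

#' Assemble an unmixing autoencoder
#'
#' Combines an encoder architecture, a decoder mixing model and the
#' abundance constraints into an untrained model description. With
#' `asc = TRUE` the latent activation is a row softmax (ANC and ASC); with
#' `asc = FALSE` it is the softly rectified tanh (ANC only, see
#' [soft_rectified_tanh()]). The decoder weight matrix is constrained
#' nonnegative by projection after every optimizer step.
#'
#' @param b Number of bands.
#' @param m Latent dimension (number of endmembers to learn).
#' @param encoder Encoder kind (see [encoder_spec()]) or an `encoder_spec`.
#' @param decoder `"linear"` or `"fan"`.
#' @param asc Enforce the sum-to-one constraint (default `TRUE`).
#' @param gamma Sharpness of the soft-rectified tanh (default 10).
#' @param decoder_init Optional [endmember_set()] used to initialize the
#'   decoder weights (`W = t(signatures)`).
#' @param decoder_fixed Freeze the decoder at its initialization (nonblind
#'   unmixing against known endmembers).
#' @return A list of class `ae_model`.
#' @export
ae_model <- function(b, m, encoder = "dense", decoder = c("linear", "fan"),
                     asc = TRUE, gamma = 10, decoder_init = NULL,
                     decoder_fixed = FALSE) {
  decoder <- match.arg(decoder)
  if (!inherits(encoder, "encoder_spec")) {
    encoder <- encoder_spec(encoder, b = b, m = m)
  }
  if (decoder_fixed && is.null(decoder_init)) {
    rmx_abort("A fixed decoder requires `decoder_init` endmembers.",
              "ramanmix_error_param")
  }
  if (!is.null(decoder_init)) {
    stopifnot(inherits(decoder_init, "endmember_set"),
              ncol(decoder_init$signatures) == b,
              nrow(decoder_init$signatures) == m)
  }
  structure(list(b = b, m = m, encoder = encoder, decoder_kind = decoder,
                 asc = asc, gamma = gamma, decoder_init = decoder_init,
                 decoder_fixed = decoder_fixed),
            class = "ae_model")
}

glorot <- function(nin, nout, dims = c(nin, nout)) {
  s <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -s, s), dims)
}

init_params <- function(model) {
  es <- model$encoder
  b <- model$b; m <- model$m
  p <- list()
  dense_in <- b
  if (es$kind %in% c("conv", "conv_transformer")) {
    p$conv.w3 <- glorot(3, 16, c(3, 16))
    p$conv.b3 <- numeric(16)
    p$conv.w5 <- glorot(5, 16, c(5, 16))
    p$conv.b5 <- numeric(16)
    if (es$kind == "conv") {
      p$conv.merge_u <- glorot(32, 1, c(32))
      p$conv.merge_b <- 0
    }
  }
  if (es$kind %in% c("transformer", "conv_transformer")) {
    D <- es$embed_dim; hd <- es$head_dim; H <- es$n_heads
    if (es$kind == "transformer") {
      p$tr.we <- glorot(1, D, c(D))
      p$tr.be <- numeric(D)
    }
    p$tr.wq <- glorot(D, H * hd)
    p$tr.wk <- glorot(D, H * hd)
    p$tr.wv <- glorot(D, H * hd)
    p$tr.wo <- glorot(H * hd, D)
    p$tr.ln1_g <- rep(1, D); p$tr.ln1_b <- numeric(D)
    p$tr.ff_w1 <- glorot(D, es$ff_dim); p$tr.ff_b1 <- numeric(es$ff_dim)
    p$tr.ff_w2 <- glorot(es$ff_dim, D); p$tr.ff_b2 <- numeric(D)
    p$tr.ln2_g <- rep(1, D); p$tr.ln2_b <- numeric(D)
    dense_in <- D
  }
  widths <- c(dense_in, es$hidden, m)
  for (i in seq_len(length(widths) - 1)) {
    p[[paste0("enc.w", i)]] <- glorot(widths[i], widths[i + 1])
    p[[paste0("enc.b", i)]] <- numeric(widths[i + 1])
  }
  p$dec.W <- if (!is.null(model$decoder_init)) {
    t(model$decoder_init$signatures)
  } else {
    pmax(glorot(m, b, c(b, m)), 0)
  }
  p
}

sinusoidal_encoding <- function(L, D) {
  pos <- seq_len(L) - 1
  enc <- matrix(0, L, D)
  for (d in seq_len(D)) {
    k <- (d - 1) %/% 2
    w <- 1 / 10000^(2 * k / D)
    enc[, d] <- if (d %% 2 == 1) sin(pos * w) else cos(pos * w)
  }
  enc
}

# forward pass: returns list(z = latent node, xhat = reconstruction node)
ae_forward <- function(model, nodes, Xb, training = FALSE) {
  es <- model$encoder
  x <- ad_const(Xb)
  if (es$kind %in% c("conv", "conv_transformer")) {
    c3 <- ad_relu3(ad_conv1d(x, nodes$conv.w3, nodes$conv.b3))
    c5 <- ad_relu3(ad_conv1d(x, nodes$conv.w5, nodes$conv.b5))
    feat <- ad_concat_channels(c3, c5)            # B x b x 32
    if (es$kind == "conv") {
      h <- ad_channel_merge(feat, nodes$conv.merge_u, nodes$conv.merge_b)
    } else {
      tokens <- feat
    }
  }
  if (es$kind == "transformer") {
    tokens <- ad_scalar_embed(x, nodes$tr.we, nodes$tr.be)
  }
  if (es$kind %in% c("transformer", "conv_transformer")) {
    if (isTRUE(es$positional_encoding)) {
      dmv <- dim(tokens$value)
      pe <- sinusoidal_encoding(dmv[2], dmv[3])
      pe3 <- array(rep(pe, each = dmv[1]), dmv)
      tokens <- ad_add(tokens, ad_const(pe3))
    }
    att <- ad_mha(tokens, nodes$tr.wq, nodes$tr.wk, nodes$tr.wv, nodes$tr.wo,
                  es$n_heads)
    att <- ad_dropout(att, es$dropout, training)
    t1 <- ad_layernorm3(ad_add(tokens, att), nodes$tr.ln1_g, nodes$tr.ln1_b)
    ff <- ad_linear3(ad_relu3(ad_linear3(t1, nodes$tr.ff_w1, nodes$tr.ff_b1)),
                     nodes$tr.ff_w2, nodes$tr.ff_b2)
    ff <- ad_dropout(ff, es$dropout, training)
    t2 <- ad_layernorm3(ad_add(t1, ff), nodes$tr.ln2_g, nodes$tr.ln2_b)
    h <- ad_mean_tokens(t2)                       # B x D
  }
  if (es$kind == "dense" || es$kind == "deep_dense") h <- x
  n_dense <- length(es$hidden) + 1
  for (i in seq_len(n_dense)) {
    h <- ad_add_bias(ad_matmul(h, nodes[[paste0("enc.w", i)]]),
                     nodes[[paste0("enc.b", i)]])
    if (i < n_dense) h <- ad_leaky_relu(h, es$leaky_slope)
  }
  z <- if (model$asc) {
    ad_softmax_rows(h)
  } else {
    ad_softplus_gamma(ad_tanh(h), model$gamma)
  }
  W <- nodes$dec.W
  xhat <- ad_matmul(z, ad_transpose(W))
  if (model$decoder_kind == "fan") {
    xhat <- ad_add(ad_add(xhat, ad_mul(xhat, xhat)),
                   ad_scale(ad_matmul(ad_mul(z, z),
                                      ad_transpose(ad_mul(W, W))), -1))
  }
  list(z = z, xhat = xhat)
}

ad_transpose <- function(a) {
  ad_node(t(a$value), list(a), function(nd) acc_grad(a, t(nd$grad)))
}

#' Train an unmixing autoencoder
#'
#' Runs self-supervised minibatch training with the Adam optimizer. After
#' every optimizer step the decoder weight matrix is projected onto the
#' nonnegative orthant (negative entries clipped to zero), so endmember
#' nonnegativity holds at every checkpoint. Training is deterministic given
#' `(config$seed, config, data)`.
#'
#' @param model An [ae_model()].
#' @param d A [spectral_dataset()] with at least one spectrum and `b` bands.
#' @param config A [training_config()].
#' @return An object of class `ae_fit`: the model, trained parameters,
#'   per-epoch mean training loss (`loss_trace`), per-epoch minimum decoder
#'   weight (`min_W_trace`), and the config.
#' @export
fit_autoencoder <- function(model, d, config = training_config()) {
  stopifnot(inherits(model, "ae_model"), inherits(config, "training_config"))
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  if (ncol(X) != model$b) {
    rmx_abort(sprintf("Dataset has %d bands but the model expects %d.",
                      ncol(X), model$b), "ramanmix_error_dim")
  }
  N <- nrow(X)
  if (N < 1) rmx_abort("Need at least one spectrum.", "ramanmix_error_data")
  set.seed(as.integer(config$seed))
  params <- init_params(model)
  opt_m <- lapply(params, function(p) p * 0)
  opt_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0
  lambda <- if (config$loss == "sad_mse") config$lambda else 0
  trainable <- names(params)
  if (model$decoder_fixed) trainable <- setdiff(trainable, "dec.W")
  loss_trace <- numeric(config$epochs)
  min_W_trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(N) else seq_len(N)
    starts <- seq(1, N, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, N)]
      Xb <- X[rows, , drop = FALSE]
      nodes <- lapply(params, ad_param)
      fwd <- ae_forward(model, nodes, Xb, training = TRUE)
      loss <- ad_recon_loss(fwd$xhat, Xb, lambda)
      if (!is.finite(loss$value)) {
        rmx_abort(sprintf("Training diverged (non-finite loss) at epoch %d, batch %d.",
                          epoch, bi), "ramanmix_error_divergence")
      }
      batch_losses[bi] <- loss$value
      ad_backward(loss)
      t_step <- t_step + 1
      corr <- sqrt(1 - beta2^t_step) / (1 - beta1^t_step)
      for (nm in trainable) {
        g <- nodes[[nm]]$grad
        if (is.null(g)) next
        opt_m[[nm]] <- beta1 * opt_m[[nm]] + (1 - beta1) * g
        opt_v[[nm]] <- beta2 * opt_v[[nm]] + (1 - beta2) * g * g
        params[[nm]] <- params[[nm]] -
          config$learning_rate * corr * opt_m[[nm]] / (sqrt(opt_v[[nm]]) + eps)
      }
      params$dec.W <- pmax(params$dec.W, 0)   # project onto W >= 0
    }
    loss_trace[epoch] <- mean(batch_losses)
    min_W_trace[epoch] <- min(params$dec.W)
  }
  structure(list(model = model, params = params, loss_trace = loss_trace,
                 min_W_trace = min_W_trace, config = config,
                 n_train = N),
            class = "ae_fit")
}

#' @exportS3Method base::print
print.ae_fit <- function(x, ...) {
  cat(sprintf("<ae_fit> %s encoder, %s decoder, m = %d; %d epochs, final loss %.5g\n",
              x$model$encoder$kind, x$model$decoder_kind, x$model$m,
              length(x$loss_trace), tail(x$loss_trace, 1)))
  invisible(x)
}

#' Extract learned endmembers from a trained autoencoder
#'
#' The columns of the decoder weight matrix `W` are the learned endmember
#' signatures (returned in the row convention of [endmember_set()]). They
#' are nonnegative by the training-time projection; a column that collapsed
#' to all zeros (an unused surplus component) is lifted to a tiny constant
#' so the set stays well formed, with a warning.
#'
#' @param fit An `ae_fit` from [fit_autoencoder()].
#' @return An [endmember_set()] with `m` signatures.
#' @export
extract_endmembers <- function(fit) {
  if (!inherits(fit, "ae_fit")) {
    rmx_abort("`fit` must be a trained ae_fit (run fit_autoencoder() first).",
              "ramanmix_error_state")
  }
  M <- t(fit$params$dec.W)
  zero <- rowSums(M) == 0
  if (any(zero)) {
    warn(sprintf("%d decoder column(s) collapsed to zero; lifted to 1e-12.",
                 sum(zero)))
    M[zero, ] <- 1e-12
  }
  endmember_set(M, labels = paste0("ae_", seq_len(nrow(M))))
}

#' Infer fractional abundances with a trained encoder
#'
#' Runs the encoder (inference mode: no dropout) over the dataset and
#' returns the latent activations as abundances. Softmax rows sum to one
#' within `1e-6` (ASC); the soft-rectified tanh keeps values in
#' `(0, ~1.00005)` (ANC only).
#'
#' @param fit An `ae_fit`.
#' @param d A [spectral_dataset()] (or matrix) with `b` bands.
#' @param batch_size Inference batch size.
#' @return An [abundance_map()].
#' @export
infer_abundances <- function(fit, d, batch_size = 512L) {
  if (!inherits(fit, "ae_fit")) {
    rmx_abort("`fit` must be a trained ae_fit (run fit_autoencoder() first).",
              "ramanmix_error_state")
  }
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  if (ncol(X) != fit$model$b) {
    rmx_abort(sprintf("Dataset has %d bands but the model expects %d.",
                      ncol(X), fit$model$b), "ramanmix_error_dim")
  }
  nodes <- lapply(fit$params, ad_const)
  starts <- seq(1, nrow(X), by = batch_size)
  Z <- do.call(rbind, lapply(starts, function(s) {
    rows <- s:min(s + batch_size - 1, nrow(X))
    ae_forward(fit$model, nodes, X[rows, , drop = FALSE], training = FALSE)$z$value
  }))
  if (fit$model$asc) Z <- Z / rowSums(Z)      # renormalize softmax roundoff
  abundance_map(Z, anc = TRUE, asc = fit$model$asc,
                scene_shape = if (inherits(d, "spectral_dataset")) d$scene_shape)
}

#' Reconstruct spectra with a trained autoencoder
#'
#' @param fit An `ae_fit`.
#' @param d Dataset to reconstruct.
#' @return A [spectral_dataset()] of reconstructions.
#' @export
reconstruct <- function(fit, d) {
  A <- infer_abundances(fit, d)
  dec <- decoder_spec(fit$model$decoder_kind, fit$params$dec.W)
  axis <- if (inherits(d, "spectral_dataset")) d$axis
  spectral_dataset(decode(A$values, dec), axis = axis,
                   scene_shape = A$scene_shape)
}

#' @rdname tidiers
#' @export
tidy.ae_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_trace),
                 loss = x$loss_trace,
                 min_decoder_weight = x$min_W_trace)
}

#' Broom-style tidiers for fitted unmixing models
#'
#' `tidy()` on an `ae_fit` returns the per-epoch loss trace; `glance()`
#' returns a one-row model summary.
#'
#' @param x An `ae_fit`.
#' @param ... Unused.
#' @name tidiers
#' @rdname tidiers
#' @export
glance.ae_fit <- function(x, ...) {
  tibble::tibble(
    encoder = x$model$encoder$kind,
    decoder = x$model$decoder_kind,
    m = x$model$m,
    asc = x$model$asc,
    epochs = length(x$loss_trace),
    n_train = x$n_train,
    final_loss = tail(x$loss_trace, 1),
    min_decoder_weight = min(x$min_W_trace)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
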