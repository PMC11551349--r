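# Minimal reverse-mode automatic differentiation over numeric arrays.
# Nodes are environments carrying a value, an accumulated gradient, their
# parent nodes, and a backward closure; a global creation counter gives the
# topological order for the backward sweep. Supports the dense, convolutional
# and transformer encoder paths plus the linear / bilinear Fan decoders.

.ad <- new.env(parent = emptyenv())
.ad$n <- 0L

ad_node <- function(value, parents = list(), bw = NULL, req = NULL) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$req <- req %||% any(vapply(parents, function(p) p$req, logical(1)))
  .ad$n <- .ad$n + 1L
  e$id <- .ad$n
  class(e) <- "ad_node"
  e
}

ad_const <- function(x) ad_node(x, req = FALSE)
ad_param <- function(x) ad_node(x, req = TRUE)

acc_grad <- function(p, g) {
  if (!p$req) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# backward sweep from a scalar loss node
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1)
  nodes <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      nodes[[length(nodes) + 1L]] <- nd
      for (p in nd$parents) if (p$req) stack[[length(stack) + 1L]] <- p
    }
  }
  ord <- order(vapply(nodes, function(nd) nd$id, integer(1)), decreasing = TRUE)
  loss$grad <- 1
  for (nd in nodes[ord]) {
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd)
  }
  invisible(loss)
}

## ---- elementwise and linear-algebra ops (shape-generic where possible) ----

ad_matmul <- function(a, b) {
  ad_node(a$value %*% b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad %*% t(b$value))
    acc_grad(b, crossprod(a$value, nd$grad))
  })
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, nd$grad)
  })
}

# add a length-k bias vector to the columns of an n x k matrix
ad_add_bias <- function(a, bias) {
  ad_node(sweep(a$value, 2, bias$value, `+`), list(a, bias), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(bias, colSums(nd$grad))
  })
}

ad_mul <- function(a, b) {
  ad_node(a$value * b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad * b$value)
    acc_grad(b, nd$grad * a$value)
  })
}

ad_scale <- function(a, s) {
  ad_node(a$value * s, list(a), function(nd) acc_grad(a, nd$grad * s))
}

ad_leaky_relu <- function(a, slope = 0.02) {
  m <- ifelse(a$value > 0, 1, slope)
  ad_node(a$value * m, list(a), function(nd) acc_grad(a, nd$grad * m))
}

ad_relu <- function(a) ad_leaky_relu(a, 0)

ad_tanh <- function(a) {
  t <- tanh(a$value)
  ad_node(t, list(a), function(nd) acc_grad(a, nd$grad * (1 - t * t)))
}

# (1/gamma) * log(1 + exp(gamma * x)), numerically stabilized softplus
ad_softplus_gamma <- function(a, gamma) {
  gx <- gamma * a$value
  v <- ifelse(gx > 30, gx + log1p(exp(-gx)), log1p(exp(gx))) / gamma
  ad_node(v, list(a), function(nd) {
    acc_grad(a, nd$grad * stats::plogis(gx))
  })
}

ad_softmax_rows <- function(a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(nd) {
    g <- nd$grad
    acc_grad(a, s * (g - rowSums(g * s)))
  })
}

## ---- convolution (1D, zero padding, "same" length) ----

shift_cols <- function(X, k) {
  # shift columns right by k (k may be negative), zero-filled
  b <- ncol(X)
  out <- matrix(0, nrow(X), b)
  if (k >= 0) {
    if (k < b) out[, (1 + k):b] <- X[, 1:(b - k), drop = FALSE]
  } else {
    if (-k < b) out[, 1:(b + k)] <- X[, (1 - k):b, drop = FALSE]
  }
  out
}

# a: B x b single-channel input; w: taps x F filters; bias: length F
# value: B x b x F
ad_conv1d <- function(a, w, bias) {
  taps <- nrow(w$value); F <- ncol(w$value)
  r <- (taps - 1) %/% 2
  offs <- seq_len(taps) - 1L - r
  B <- nrow(a$value); b <- ncol(a$value)
  shifts <- lapply(offs, function(o) shift_cols(a$value, -o))
  out <- array(0, c(B, b, F))
  for (f in seq_len(F)) {
    acc <- matrix(bias$value[f], B, b)
    for (t in seq_len(taps)) acc <- acc + w$value[t, f] * shifts[[t]]
    out[, , f] <- acc
  }
  ad_node(out, list(a, w, bias), function(nd) {
    G <- nd$grad
    gw <- matrix(0, taps, F)
    gb <- numeric(F)
    ga <- matrix(0, B, b)
    for (f in seq_len(F)) {
      Gf <- G[, , f]
      if (is.null(dim(Gf))) Gf <- matrix(Gf, B, b)
      gb[f] <- sum(Gf)
      for (t in seq_len(taps)) {
        gw[t, f] <- sum(Gf * shifts[[t]])
        if (a$req) ga <- ga + w$value[t, f] * shift_cols(Gf, offs[t])
      }
    }
    acc_grad(w, gw)
    acc_grad(bias, gb)
    acc_grad(a, ga)
  })
}

# concatenate two B x b x F arrays along channels
ad_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a$value
  out[, , da[3] + seq_len(db[3])] <- b$value
  ad_node(out, list(a, b), function(nd) {
    acc_grad(a, nd$grad[, , seq_len(da[3]), drop = FALSE])
    acc_grad(b, nd$grad[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# position-wise linear map across channels: B x b x C -> B x b
ad_channel_merge <- function(a, u, b0) {
  C <- dim(a$value)[3]
  out <- matrix(b0$value, dim(a$value)[1], dim(a$value)[2])
  for (cc in seq_len(C)) out <- out + u$value[cc] * a$value[, , cc]
  ad_node(out, list(a, u, b0), function(nd) {
    G <- nd$grad
    gu <- vapply(seq_len(C), function(cc) sum(G * a$value[, , cc]), numeric(1))
    acc_grad(u, gu)
    acc_grad(b0, sum(G))
    if (a$req) {
      ga <- array(0, dim(a$value))
      for (cc in seq_len(C)) ga[, , cc] <- G * u$value[cc]
      acc_grad(a, ga)
    }
  })
}

## ---- 3D tensor ops for transformer paths (B x L x D) ----

as_mat3 <- function(x) matrix(x, prod(dim(x)[1:2]), dim(x)[3])

# embed scalar tokens: B x L -> B x L x D via x * we + be
ad_scalar_embed <- function(a, we, be) {
  B <- nrow(a$value); L <- ncol(a$value); D <- length(we$value)
  out <- array(0, c(B, L, D))
  for (d in seq_len(D)) out[, , d] <- a$value * we$value[d] + be$value[d]
  ad_node(out, list(a, we, be), function(nd) {
    G <- nd$grad
    gwe <- vapply(seq_len(D), function(d) sum(G[, , d] * a$value), numeric(1))
    gbe <- vapply(seq_len(D), function(d) sum(G[, , d]), numeric(1))
    acc_grad(we, gwe)
    acc_grad(be, gbe)
    if (a$req) {
      ga <- matrix(0, B, L)
      for (d in seq_len(D)) ga <- ga + G[, , d] * we$value[d]
      acc_grad(a, ga)
    }
  })
}

# linear map over the last dim of a 3D array
ad_linear3 <- function(a, w, bias = NULL) {
  dm <- dim(a$value)
  M <- as_mat3(a$value)
  out <- M %*% w$value
  if (!is.null(bias)) out <- sweep(out, 2, bias$value, `+`)
  parents <- c(list(a, w), if (!is.null(bias)) list(bias))
  ad_node(array(out, c(dm[1], dm[2], ncol(w$value))), parents, function(nd) {
    G <- as_mat3(nd$grad)
    acc_grad(w, crossprod(M, G))
    if (!is.null(bias)) acc_grad(bias, colSums(G))
    if (a$req) acc_grad(a, array(G %*% t(w$value), dm))
  })
}

ad_relu3 <- function(a) {
  m <- ifelse(a$value > 0, 1, 0)
  ad_node(a$value * m, list(a), function(nd) acc_grad(a, nd$grad * m))
}

ad_add3 <- function(a, b) ad_add(a, b)

# layer normalization over the last dim, with learned gain/bias
ad_layernorm3 <- function(a, gamma, beta, eps = 1e-5) {
  dm <- dim(a$value)
  M <- as_mat3(a$value)
  mu <- rowMeans(M)
  va <- rowMeans(M * M) - mu * mu
  inv <- 1 / sqrt(va + eps)
  Xn <- (M - mu) * inv
  out <- sweep(Xn, 2, gamma$value, `*`)
  out <- sweep(out, 2, beta$value, `+`)
  ad_node(array(out, dm), list(a, gamma, beta), function(nd) {
    G <- as_mat3(nd$grad)
    acc_grad(gamma, colSums(G * Xn))
    acc_grad(beta, colSums(G))
    if (a$req) {
      dxn <- sweep(G, 2, gamma$value, `*`)
      t1 <- rowMeans(dxn)
      t2 <- rowMeans(dxn * Xn)
      ga <- inv * (dxn - t1 - Xn * t2)
      acc_grad(a, array(ga, dm))
    }
  })
}

ad_dropout <- function(a, rate, training) {
  if (!training || rate <= 0) return(a)
  mask <- array(stats::rbinom(length(a$value), 1, 1 - rate) / (1 - rate),
                dim(a$value) %||% length(a$value))
  ad_node(a$value * mask, list(a), function(nd) acc_grad(a, nd$grad * mask))
}

# multi-head self-attention on B x L x D tokens (fused op)
ad_mha <- function(a, wq, wk, wv, wo, n_heads) {
  dm <- dim(a$value); B <- dm[1]; L <- dm[2]; D <- dm[3]
  hd <- ncol(wq$value) / n_heads
  scale <- 1 / sqrt(hd)
  cache <- vector("list", B)
  out <- array(0, c(B, L, D))
  for (i in seq_len(B)) {
    X <- matrix(a$value[i, , ], L, D)
    Q <- X %*% wq$value; K <- X %*% wk$value; V <- X %*% wv$value
    O <- matrix(0, L, ncol(wq$value))
    Ahs <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      j <- ((h - 1) * hd + 1):(h * hd)
      S <- (Q[, j, drop = FALSE] %*% t(K[, j, drop = FALSE])) * scale
      S <- S - apply(S, 1, max)
      E <- exp(S)
      A <- E / rowSums(E)
      O[, j] <- A %*% V[, j, drop = FALSE]
      Ahs[[h]] <- A
    }
    out[i, , ] <- O %*% wo$value
    cache[[i]] <- list(X = X, Q = Q, K = K, V = V, O = O, A = Ahs)
  }
  ad_node(out, list(a, wq, wk, wv, wo), function(nd) {
    gwq <- 0; gwk <- 0; gwv <- 0; gwo <- 0
    ga <- array(0, dm)
    for (i in seq_len(B)) {
      cc <- cache[[i]]
      Gy <- matrix(nd$grad[i, , ], L, D)
      gwo <- gwo + crossprod(cc$O, Gy)
      gO <- Gy %*% t(wo$value)
      gQ <- matrix(0, L, ncol(wq$value))
      gK <- gQ; gV <- gQ
      for (h in seq_len(n_heads)) {
        j <- ((h - 1) * hd + 1):(h * hd)
        A <- cc$A[[h]]
        gOh <- gO[, j, drop = FALSE]
        gA <- gOh %*% t(cc$V[, j, drop = FALSE])
        gV[, j] <- crossprod(A, gOh)
        gS <- A * (gA - rowSums(gA * A))
        gS <- gS * scale
        gQ[, j] <- gS %*% cc$K[, j, drop = FALSE]
        gK[, j] <- crossprod(gS, cc$Q[, j, drop = FALSE])
      }
      gwq <- gwq + crossprod(cc$X, gQ)
      gwk <- gwk + crossprod(cc$X, gK)
      gwv <- gwv + crossprod(cc$X, gV)
      if (a$req) {
        ga[i, , ] <- gQ %*% t(wq$value) + gK %*% t(wk$value) + gV %*% t(wv$value)
      }
    }
    acc_grad(wq, gwq); acc_grad(wk, gwk); acc_grad(wv, gwv); acc_grad(wo, gwo)
    acc_grad(a, ga)
  })
}

# mean-pool tokens: B x L x D -> B x D
ad_mean_tokens <- function(a) {
  dm <- dim(a$value)
  M <- as_mat3(a$value)                      # (B*L) x D
  B <- dm[1]; L <- dm[2]
  idx <- rep(seq_len(B), times = L)
  out <- rowsum(M, idx) / L
  ad_node(out, list(a), function(nd) {
    G <- nd$grad[idx, , drop = FALSE] / L
    acc_grad(a, array(G, dm))
  })
}

## ---- losses (fused, constant targets) ----

# mean over rows of SAD(x_i, xhat_i) + lambda * mean-over-bands squared error
ad_recon_loss <- function(xhat, X, lambda = 0) {
  Xh <- xhat$value
  N <- nrow(X); b <- ncol(X)
  nx <- pmax(sqrt(rowSums(X * X)), 1e-12)
  nh <- pmax(sqrt(rowSums(Xh * Xh)), 1e-12)
  cs <- rowSums(X * Xh) / (nx * nh)
  csc <- pmin(pmax(cs, -1 + 1e-7), 1 - 1e-7)
  loss <- mean(acos(csc))
  if (lambda > 0) loss <- loss + lambda * mean(rowMeans((Xh - X)^2))
  ad_node(loss, list(xhat), function(nd) {
    dacos <- -1 / sqrt(1 - csc * csc)
    # d cs / d xhat = x/(|x||xh|) - cs * xh/|xh|^2
    g <- (X / (nx * nh) - (cs / (nh * nh)) * Xh) * (dacos / N)
    if (lambda > 0) g <- g + (2 * lambda / (N * b)) * (Xh - X)
    acc_grad(xhat, nd$grad * g)
  })
}
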