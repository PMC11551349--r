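# Classical comparators: geometric endmember extraction (VCA, N-FINDR) and
# least-squares abundance estimation (NNLS, FCLS).

#' Vertex component analysis (VCA)
#'
#' Geometric endmember extraction under the pure-pixel assumption. The data
#' are projected to an `n`-dimensional signal subspace (truncated SVD); when
#' the estimated SNR exceeds the conventional threshold
#' `15 + 10 log10(n)` dB a projective projection is used, otherwise the data
#' are mean-removed, projected to `n - 1` components and lifted with a
#' constant coordinate. Endmembers are then found iteratively: each new one
#' is the data point with the largest projection onto a random direction
#' orthogonal to the subspace spanned by those already found. Returned
#' endmembers are rows of the input data. Deterministic given `seed`; ties
#' in the extreme-point search break to the lowest pixel index.
#'
#' @param d A [spectral_dataset()] (or numeric matrix, spectra in rows).
#' @param n Number of endmembers to extract.
#' @param seed Seed for the random projection directions.
#' @return An [endmember_set()] with attribute `indices` (selected pixel
#'   rows).
#' @export
vca <- function(d, n, seed = 1L) {
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  N <- nrow(X); b <- ncol(X)
  if (N < n) {
    rmx_abort(sprintf("VCA needs at least n = %d spectra, got %d.", n, N),
              "ramanmix_error_data")
  }
  Y <- t(X)                                   # b x N, columns are spectra
  mu <- rowMeans(Y)
  Y0 <- Y - mu
  svd_d <- svd(Y0, nu = min(n, b), nv = 0)
  Ud <- svd_d$u[, seq_len(min(n, b)), drop = FALSE]
  x_p <- crossprod(Ud, Y0)                    # n x N
  P_y <- sum(Y^2) / N
  P_x <- sum(x_p^2) / N + sum((crossprod(Ud, mu))^2)
  snr <- 10 * log10(max((P_x - (n / b) * P_y), .Machine$double.eps) /
                      max(P_y - P_x, .Machine$double.eps))
  snr_th <- 15 + 10 * log10(n)

  if (snr > snr_th) {
    dd <- n
    svd_f <- svd(Y, nu = dd, nv = 0)
    Ud <- svd_f$u[, seq_len(dd), drop = FALSE]
    x_p <- crossprod(Ud, Y)
    u <- rowMeans(x_p)
    denom <- colSums(x_p * u)
    denom[denom == 0] <- .Machine$double.eps
    Yp <- x_p / matrix(denom, dd, N, byrow = TRUE)   # projective projection
  } else {
    dd <- max(n - 1, 1)
    Udm <- svd_d$u[, seq_len(dd), drop = FALSE]
    x_p <- crossprod(Udm, Y0)
    c_const <- max(sqrt(colSums(x_p^2)))
    Yp <- rbind(x_p, c_const)                        # lift to n dims
  }

  p <- nrow(Yp)
  set.seed(as.integer(seed))
  A <- matrix(0, p, n); A[p, 1] <- 1
  idx <- integer(n)
  for (i in seq_len(n)) {
    w <- rnorm(p)
    f <- w - A %*% pracma::pinv(A) %*% w
    nf <- sqrt(sum(f^2))
    f <- if (nf > 0) f / nf else f
    v <- abs(crossprod(Yp, f))
    idx[i] <- which.max(v)                  # which.max takes lowest on ties
    A[, i] <- Yp[, idx[i]]
  }
  out <- endmember_set(nonneg_signatures(X[idx, , drop = FALSE]),
                       labels = paste0("vca_", seq_len(n)))
  attr(out, "indices") <- idx
  out
}

# selected pixels may dip below zero (dark noise); endmember signatures are
# nonnegative by convention, so project onto the nonnegative orthant
nonneg_signatures <- function(M) {
  M <- pmax(M, 0)
  zero <- rowSums(M) == 0
  if (any(zero)) M[zero, ] <- 1e-12
  M
}

# simplex volume proxy in reduced space: |det([1; vertices])|
simplex_volume <- function(V) {
  # V: n x (n-1) matrix of vertex coordinates
  abs(det(cbind(1, V)))
}

#' N-FINDR endmember extraction
#'
#' Inflates a simplex inside the data cloud: starting from `n` random
#' distinct pixels, every pixel is tested in every vertex position and a
#' replacement is accepted whenever it increases the simplex volume
#' (computed as `|det([1; vertices])|` in an `(n-1)`-dimensional principal
#' subspace). Sweeps repeat until no swap improves the volume or
#' `max_sweeps` is reached. Returns rows of the input data; deterministic
#' given `seed`.
#'
#' @inheritParams vca
#' @param max_sweeps Maximum full replacement sweeps (default 10).
#' @return An [endmember_set()] with attributes `indices` and
#'   `volume_trace` (volume after each accepted swap, non-decreasing).
#' @export
nfindr <- function(d, n, seed = 1L, max_sweeps = 10L) {
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  N <- nrow(X)
  if (N < n) {
    rmx_abort(sprintf("N-FINDR needs at least n = %d spectra, got %d.", n, N),
              "ramanmix_error_data")
  }
  # reduce to n-1 principal components
  if (n > 1) {
    pc <- prcomp(X, center = TRUE, rank. = n - 1)
    Z <- pc$x[, seq_len(n - 1), drop = FALSE]
  } else {
    Z <- matrix(0, N, 0)
  }
  set.seed(as.integer(seed))
  # initialize from pixels with distinct spectra: duplicated rows (common in
  # patchwise-constant scenes) would start the simplex at zero volume, where
  # no single replacement can improve it
  uniq <- which(!duplicated(Z))
  if (length(uniq) < n) {
    rmx_abort(sprintf("Only %d distinct spectra; cannot seat an n = %d simplex.",
                      length(uniq), n), "ramanmix_error_data")
  }
  idx <- sample(uniq, n)
  vol <- simplex_volume(Z[idx, , drop = FALSE])
  trace <- vol
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      cand <- idx
      vols <- vapply(seq_len(N), function(j) {
        cand[i] <- j
        simplex_volume(Z[cand, , drop = FALSE])
      }, numeric(1))
      jbest <- which.max(vols)
      if (vols[jbest] > vol && !(jbest %in% idx)) {
        idx[i] <- jbest
        vol <- vols[jbest]
        trace <- c(trace, vol)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  out <- endmember_set(nonneg_signatures(X[idx, , drop = FALSE]),
                       labels = paste0("nfindr_", seq_len(n)))
  attr(out, "indices") <- idx
  attr(out, "volume_trace") <- trace
  out
}

#' Non-negative least-squares abundances (NNLS)
#'
#' Per spectrum `x`, solves `min_{alpha >= 0} || t(M) alpha - x ||_2` with
#' the Lawson--Hanson active-set algorithm (`pracma::lsqnonneg`). Imposes
#' the ANC only.
#'
#' @param M An [endmember_set()] (`n x b`).
#' @param d A [spectral_dataset()] (or matrix, spectra in rows).
#' @return An [abundance_map()] with `anc = TRUE, asc = FALSE`.
#' @export
nnls_abundance <- function(M, d) {
  stopifnot(inherits(M, "endmember_set"))
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  C <- t(M$signatures)                        # b x n
  A <- t(apply(X, 1, function(x) {
    if (all(x == 0)) return(numeric(ncol(C)))
    pracma::lsqnonneg(C, x)$x
  }))
  if (nrow(M$signatures) == 1) A <- t(A)
  abundance_map(A, anc = TRUE, asc = FALSE,
                scene_shape = if (inherits(d, "spectral_dataset")) d$scene_shape)
}

#' Fully constrained least-squares abundances (FCLS)
#'
#' Imposes both the ANC and the ASC. Realized with the standard augmented
#' system: a constant row of weight `delta` is appended to `t(M)` and `x`,
#' softly enforcing `sum(alpha) = 1` inside an NNLS solve; the result is
#' then renormalized to sum to exactly 1 (tolerance 1e-6 by construction).
#'
#' @inheritParams nnls_abundance
#' @param delta Weight of the sum-to-one row (default `1e5`).
#' @return An [abundance_map()] with `anc = TRUE, asc = TRUE`.
#' @export
fcls_abundance <- function(M, d, delta = 1e5) {
  stopifnot(inherits(M, "endmember_set"), delta > 0)
  X <- if (inherits(d, "spectral_dataset")) d$intensities else as.matrix(d)
  n <- nrow(M$signatures)
  Mt <- t(M$signatures)
  # The active-set solver can stall on the extreme row scaling of a large
  # delta with near-collinear endmembers; since the solution is renormalized
  # to an exact sum of one afterwards, it is insensitive to the precise
  # weight, so back off delta by decades until the solve succeeds.
  deltas <- unique(pmax(delta / 10^(0:3), 100))
  solve_one <- function(x) {
    for (dl in deltas) {
      a <- tryCatch(pracma::lsqnonneg(rbind(Mt, dl), c(x, dl))$x,
                    error = function(e) NULL)
      if (!is.null(a)) {
        s <- sum(a)
        return(if (s > 0) a / s else rep(1 / n, n))
      }
    }
    rep(1 / n, n)                             # degenerate spectrum
  }
  A <- t(apply(X, 1, solve_one))
  if (n == 1) A <- t(A)
  abundance_map(A, anc = TRUE, asc = TRUE,
                scene_shape = if (inherits(d, "spectral_dataset")) d$scene_shape)
}
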