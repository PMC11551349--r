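# Preprocessing steps for experimental Raman spectra: spectral cropping,
# cosmic-spike removal, Savitzky-Golay denoising, asymmetric least-squares
# baseline correction, and global normalization, plus two named pipeline
# presets ("sugar", "cell").

#' Crop a dataset to a wavenumber window
#'
#' Retains exactly the bands whose axis value lies in the closed interval
#' `[lo, hi]` (membership by wavenumber, not index).
#'
#' @param d A [spectral_dataset()].
#' @param lo,hi Window bounds in cm^-1, `lo < hi`.
#' @return The cropped dataset (scene geometry preserved).
#' @export
crop_spectra <- function(d, lo, hi) {
  stopifnot(inherits(d, "spectral_dataset"), lo < hi)
  keep <- which(d$axis >= lo & d$axis <= hi)
  if (length(keep) < 2) {
    rmx_abort(sprintf("Crop window [%g, %g] retains %d band(s) of axis [%g, %g].",
                      lo, hi, length(keep), d$axis[1], d$axis[length(d$axis)]),
              "ramanmix_error_empty_range")
  }
  spectral_dataset(d$intensities[, keep, drop = FALSE], d$axis[keep],
                   d$scene_shape)
}

# modified z-scores of the first differences of one spectrum
modified_zscores <- function(y) {
  dy <- diff(y)
  med <- median(dy)
  madv <- median(abs(dy - med))
  if (madv == 0) madv <- .Machine$double.eps
  0.6745 * (dy - med) / madv
}

despike_one <- function(y, kernel, z_threshold) {
  z <- abs(modified_zscores(y))
  spike <- c(FALSE, z > z_threshold) | c(z > z_threshold, FALSE)
  if (!any(spike)) return(y)
  b <- length(y)
  out <- y
  for (i in which(spike)) {
    lo <- max(1, i - kernel); hi <- min(b, i + kernel)
    neigh <- setdiff(lo:hi, which(spike))
    out[i] <- if (length(neigh) > 0) mean(y[neigh]) else median(y)
  }
  out
}

#' Remove cosmic spikes (modified z-score despiking)
#'
#' Detects cosmic spikes as bands whose modified z-score of first
#' differences, `0.6745 * (grad - median(grad)) / MAD(grad)`, exceeds
#' `z_threshold` in absolute value, and replaces each flagged band with the
#' mean of the non-spike bands within `kernel` bands on either side
#' (one-sided at the spectrum boundaries). Spectra with no excursions pass
#' through unchanged.
#'
#' @param d A [spectral_dataset()].
#' @param kernel Half-width (bands) of the replacement neighborhood
#'   (default 3).
#' @param z_threshold Modified z-score threshold (default 8).
#' @return The despiked dataset.
#' @export
despike <- function(d, kernel = 3L, z_threshold = 8) {
  stopifnot(inherits(d, "spectral_dataset"), kernel >= 1)
  X <- d$intensities
  X2 <- t(apply(X, 1, despike_one, kernel = as.integer(kernel),
                z_threshold = z_threshold))
  spectral_dataset(X2, d$axis, d$scene_shape)
}

#' Savitzky-Golay denoising
#'
#' Replaces each spectrum with its sliding local least-squares polynomial
#' fit (`signal::sgolayfilt`). The defaults are a cubic polynomial over a
#' 7-band window.
#'
#' @param d A [spectral_dataset()].
#' @param window Odd window length (bands).
#' @param polyorder Polynomial order, `< window`.
#' @return The smoothed dataset.
#' @export
denoise_savgol <- function(d, window = 7L, polyorder = 3L) {
  stopifnot(inherits(d, "spectral_dataset"))
  if (window %% 2 == 0 || polyorder >= window) {
    rmx_abort("`window` must be odd and greater than `polyorder`.",
              "ramanmix_error_param")
  }
  if (window > ncol(d$intensities)) {
    rmx_abort(sprintf("Window %d exceeds the band count %d.",
                      window, ncol(d$intensities)), "ramanmix_error_param")
  }
  X2 <- t(apply(d$intensities, 1, signal::sgolayfilt,
                p = polyorder, n = window))
  spectral_dataset(X2, d$axis, d$scene_shape)
}

# second-difference penalty matrix D'D as a sparse band matrix
whittaker_penalty <- function(b, diff_order = 2) {
  coefs <- choose(diff_order, 0:diff_order) * (-1)^(0:diff_order)
  D <- Matrix::bandSparse(b - diff_order, b, k = 0:diff_order,
                          diagonals = lapply(coefs, rep, b))
  Matrix::crossprod(D)
}

asls_baseline_one <- function(y, lambda, p, DtD, max_iter, tol) {
  b <- length(y)
  w <- rep(1, b)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(b, w)
    z_new <- as.numeric(Matrix::solve(W + lambda * DtD, w * y))
    w_new <- ifelse(y > z_new, p, 1 - p)
    delta <- sqrt(sum((z_new - z)^2)) / max(sqrt(sum(z^2)), .Machine$double.eps)
    z <- z_new
    if (it > 1 && delta < tol) break
    if (all(w_new == w)) { w <- w_new; break }
    w <- w_new
  }
  z
}

aspls_baseline_one <- function(y, lambda, DtD, max_iter, tol) {
  b <- length(y)
  w <- rep(1, b)
  alpha <- rep(1, b)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(b, w)
    P <- Matrix::Diagonal(b, lambda * alpha)
    z_new <- as.numeric(Matrix::solve(W + P %*% DtD, w * y))
    r <- y - z_new
    r_neg <- r[r < 0]
    s <- if (length(r_neg) > 1) sd(r_neg) else .Machine$double.eps
    # logistic reweighting of points above the baseline; adaptive penalty
    # scaled by the local residual magnitude
    w_new <- 1 / (1 + exp(2 * (r - s) / s))
    alpha <- abs(r) / max(abs(r))
    delta <- sqrt(sum((w_new - w)^2)) / max(sqrt(sum(w^2)), .Machine$double.eps)
    w <- w_new
    z <- z_new
    if (delta < tol) break
  }
  z
}

#' Baseline correction by (adaptive) asymmetric least squares
#'
#' Estimates a smooth baseline with a Whittaker smoother penalized by the
#' `diff_order`-th differences and subtracts it from each spectrum.
#'
#' * `method = "asls"` — asymmetric least squares: points above the current
#'   baseline get weight `p`, points below `1 - p`, iterated to convergence.
#' * `method = "aspls"` — adaptive variant: weights follow a logistic
#'   function of the residuals and the smoothing penalty is locally scaled
#'   by the normalized residual magnitude, removing the need to choose `p`.
#'
#' @param d A [spectral_dataset()].
#' @param method `"asls"` or `"aspls"`.
#' @param lambda Smoothness penalty (default `1e6` for AsLS, `1e5` for
#'   ASPLS).
#' @param p Asymmetry weight for AsLS (default 0.01); ignored for ASPLS.
#' @param diff_order Difference order of the penalty matrix (default 2).
#' @param max_iter Maximum reweighting iterations.
#' @param tol Relative-change exit tolerance (default 0.001).
#' @return The baseline-corrected dataset; the estimated baselines are
#'   attached as attribute `"baselines"` (`N x b` matrix).
#' @export
baseline_correct <- function(d, method = c("asls", "aspls"), lambda = NULL,
                             p = 0.01, diff_order = 2L, max_iter = NULL,
                             tol = 0.001) {
  stopifnot(inherits(d, "spectral_dataset"))
  method <- match.arg(method)
  lambda <- lambda %||% if (method == "asls") 1e6 else 1e5
  max_iter <- max_iter %||% if (method == "asls") 50L else 100L
  if (lambda <= 0) rmx_abort("`lambda` must be positive.", "ramanmix_error_param")
  if (method == "asls" && (p <= 0 || p >= 1)) {
    rmx_abort("`p` must be in (0, 1).", "ramanmix_error_param")
  }
  b <- ncol(d$intensities)
  DtD <- whittaker_penalty(b, diff_order)
  Z <- t(apply(d$intensities, 1, function(y) {
    if (all(y == 0)) return(numeric(b))
    if (method == "asls") asls_baseline_one(y, lambda, p, DtD, max_iter, tol)
    else aspls_baseline_one(y, lambda, DtD, max_iter, tol)
  }))
  out <- spectral_dataset(d$intensities - Z, d$axis, d$scene_shape)
  attr(out, "baselines") <- Z
  out
}

#' Global normalization
#'
#' * `"global_vector"` — divides every value by the single dataset-wide
#'   maximum absolute intensity (max |value| becomes exactly 1).
#' * `"global_minmax"` — affinely maps the dataset-wide `[min, max]` onto
#'   `[0, 1]`.
#'
#' Both modes are global over the whole dataset, preserving relative
#' intensities between spectra.
#'
#' @param d A [spectral_dataset()].
#' @param mode `"global_vector"` or `"global_minmax"`.
#' @return The normalized dataset.
#' @export
normalize_spectra <- function(d, mode = c("global_vector", "global_minmax")) {
  stopifnot(inherits(d, "spectral_dataset"))
  mode <- match.arg(mode)
  X <- d$intensities
  X2 <- if (mode == "global_vector") {
    m <- max(abs(X))
    if (m == 0) rmx_abort("All-zero dataset cannot be vector-normalized.",
                          "ramanmix_error_degenerate")
    X / m
  } else {
    lo <- min(X); hi <- max(X)
    if (hi == lo) rmx_abort("Constant dataset has no min-max range.",
                            "ramanmix_error_degenerate")
    (X - lo) / (hi - lo)
  }
  spectral_dataset(X2, d$axis, d$scene_shape)
}

#' Preprocessing pipeline presets
#'
#' Returns the ordered step list of one of the two built-in recipes:
#'
#' * `"sugar"` — crop to 400--1800 cm^-1; ASPLS baseline correction
#'   (`lambda = 1e5`, difference order 2, 100 iterations, tolerance 0.001);
#'   global vector normalization.
#' * `"cell"` — crop to the fingerprint region 700--1800 cm^-1; despiking
#'   (kernel 3, z-threshold 8); Savitzky-Golay denoising (cubic, window 7);
#'   AsLS baseline correction (`lambda = 1e6`, `p = 0.01`, difference order
#'   2, 50 iterations, tolerance 0.001); global min-max normalization to
#'   `[0, 1]`.
#'
#' @param preset `"sugar"` or `"cell"`.
#' @return A list of class `preprocess_pipeline`: named steps, each a list
#'   of a function name and its arguments.
#' @export
preprocess_preset <- function(preset = c("sugar", "cell")) {
  preset <- match.arg(preset)
  steps <- if (preset == "sugar") {
    list(
      crop = list(fn = "crop_spectra", args = list(lo = 400, hi = 1800)),
      baseline = list(fn = "baseline_correct",
                      args = list(method = "aspls", lambda = 1e5,
                                  diff_order = 2L, max_iter = 100L,
                                  tol = 0.001)),
      normalize = list(fn = "normalize_spectra",
                       args = list(mode = "global_vector"))
    )
  } else {
    list(
      crop = list(fn = "crop_spectra", args = list(lo = 700, hi = 1800)),
      despike = list(fn = "despike", args = list(kernel = 3L, z_threshold = 8)),
      denoise = list(fn = "denoise_savgol",
                     args = list(window = 7L, polyorder = 3L)),
      baseline = list(fn = "baseline_correct",
                      args = list(method = "asls", lambda = 1e6, p = 0.01,
                                  diff_order = 2L, max_iter = 50L,
                                  tol = 0.001)),
      normalize = list(fn = "normalize_spectra",
                       args = list(mode = "global_minmax"))
    )
  }
  structure(list(preset = preset, steps = steps), class = "preprocess_pipeline")
}

#' Apply a preprocessing pipeline
#'
#' Runs the steps of a [preprocess_preset()] (or a hand-built pipeline of
#' the same shape) in order. Individual step parameters can be overridden
#' via `overrides`, e.g. `overrides = list(crop = list(lo = 600))`.
#'
#' @param d A [spectral_dataset()].
#' @param pipeline A `preprocess_pipeline`, or a preset name.
#' @param overrides Named list of per-step argument overrides.
#' @return The processed dataset, with attribute `"log"`: a character vector
#'   describing each executed step and its parameters.
#' @export
apply_pipeline <- function(d, pipeline = "cell", overrides = list()) {
  if (is.character(pipeline)) pipeline <- preprocess_preset(pipeline)
  stopifnot(inherits(pipeline, "preprocess_pipeline"))
  log <- character()
  for (nm in names(pipeline$steps)) {
    step <- pipeline$steps[[nm]]
    args <- utils::modifyList(step$args, overrides[[nm]] %||% list())
    d <- do.call(step$fn, c(list(d), args))
    log <- c(log, sprintf("%s: %s(%s)", nm, step$fn,
                          paste(names(args), vapply(args, format, character(1)),
                                sep = "=", collapse = ", ")))
  }
  attr(d, "log") <- log
  d
}
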