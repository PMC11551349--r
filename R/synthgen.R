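# Synthetic Raman mixture generator: Gaussian-peak endmembers, abundance
# scenes (chessboard / gaussian / dirichlet), linear or bilinear Fan mixing,
# and artifact injection (dark noise, arctan baseline, cosmic spikes).

#' Endmember sampler parameters
#'
#' Parameters of the stochastic law used to draw synthetic Raman endmembers.
#' Each endmember is a superposition of `npeaks ~ U{5..9}` Gaussian peaks
#' over `b` bands. A peak has height `h = h1 * h2` with `h1 = 1 + 5*hbeta`,
#' `hbeta ~ Beta(1, 3)`, and `h2 ~ U(0.1, 1)`; center `bp ~ U(10, b - 10)`
#' (band units, keeping a 10-band margin); and width `sigma_p = wp * sigma`
#' with `sigma ~ U(0.1, 1)` in band units. Clean endmembers use `wp = 1`;
#' noisy endmembers additionally superpose `U{50..99}` small peaks drawn with
#' `h1 = 1/3` and `wp = 2`, emulating the subtle secondary structure of
#' experimental Raman signatures.
#'
#' @param b Number of spectral bands (default 1000).
#' @param noisy Logical; add the small-peak population.
#' @param npeaks_range Integer range of major peak counts.
#' @param small_peaks_range Integer range of small peak counts (noisy only).
#' @param h1_beta Shape parameters of the Beta law behind `h1`.
#' @param h1_scale Multiplier in `h1 = 1 + h1_scale * hbeta`.
#' @param h2_range Uniform range of the secondary height factor.
#' @param center_margin Margin (bands) kept free of peak centers at both ends.
#' @param sigma_range Uniform range of the base width draw (bands).
#' @param wp_clean,wp_small Width multipliers for major and small peaks.
#' @param h1_small Fixed `h1` of small peaks.
#' @param width_multiplier Extra multiplier applied to every peak width
#'   (default 1, i.e. the law above taken at face value; larger values give
#'   broader, more band-overlapping peaks).
#' @return A list of class `endmember_params`.
#' @export
endmember_params <- function(b = 1000L, noisy = FALSE,
                             npeaks_range = c(5L, 9L),
                             small_peaks_range = c(50L, 99L),
                             h1_beta = c(1, 3), h1_scale = 5,
                             h2_range = c(0.1, 1),
                             center_margin = 10,
                             sigma_range = c(0.1, 1),
                             wp_clean = 1, wp_small = 2, h1_small = 1 / 3,
                             width_multiplier = 1) {
  b <- as.integer(b)
  if (b < 2 * center_margin + 1) {
    rmx_abort(sprintf("b = %d leaves no room for peak centers with margin %g.",
                      b, center_margin), "ramanmix_error_param")
  }
  structure(as.list(environment()), class = "endmember_params")
}

# one endmember as a length-b vector of superposed Gaussian peaks; the
# per-peak draws are recorded so the stochastic law is testable
sample_endmember_vector <- function(p) {
  j <- seq_len(p$b)
  draw_peaks <- function(npeaks, h1, wp, kind) {
    s <- numeric(p$b)
    tab <- vector("list", npeaks)
    for (k in seq_len(npeaks)) {
      h2 <- runif(1, p$h2_range[1], p$h2_range[2])
      hp <- h1[min(k, length(h1))] * h2
      bp <- runif(1, p$center_margin, p$b - p$center_margin)
      sigma <- wp * runif(1, p$sigma_range[1], p$sigma_range[2]) * p$width_multiplier
      s <- s + hp * exp(-(j - bp)^2 / (2 * sigma^2))
      tab[[k]] <- c(h1 = h1[min(k, length(h1))], h2 = h2, height = hp,
                    center = bp, sigma = sigma)
    }
    list(s = s, tab = cbind(do.call(rbind, tab), kind = kind))
  }
  npeaks <- sample(p$npeaks_range[1]:p$npeaks_range[2], 1)
  h1 <- 1 + p$h1_scale * rbeta(npeaks, p$h1_beta[1], p$h1_beta[2])
  major <- draw_peaks(npeaks, h1, p$wp_clean, kind = 1)
  spec <- major$s
  peaks <- major$tab
  nsmall <- 0L
  if (isTRUE(p$noisy)) {
    nsmall <- sample(p$small_peaks_range[1]:p$small_peaks_range[2], 1)
    small <- draw_peaks(nsmall, p$h1_small, p$wp_small, kind = 2)
    spec <- spec + small$s
    peaks <- rbind(peaks, small$tab)
  }
  attr(spec, "npeaks") <- npeaks
  attr(spec, "nsmall") <- nsmall
  attr(spec, "peaks") <- peaks
  spec
}

#' Sample synthetic Raman endmembers
#'
#' Draws `n` endmembers from the Gaussian-peak superposition law described in
#' [endmember_params()]. Uses R's global RNG stream; call `set.seed()` (or go
#' through [generate_raman_dataset()], which manages per-stage streams) for
#' reproducibility.
#'
#' @param n Number of endmembers.
#' @param params An `endmember_params` object.
#' @return An [endmember_set()] with attributes `npeaks` and `nsmall` (the
#'   per-endmember peak counts) and `peaks` (a matrix of every per-peak draw:
#'   `h1`, `h2`, `height`, `center`, `sigma`, `kind` with 1 = major,
#'   2 = small).
#' @export
sample_endmembers <- function(n = 5L, params = endmember_params()) {
  stopifnot(n >= 1)
  specs <- lapply(seq_len(n), function(i) sample_endmember_vector(params))
  M <- do.call(rbind, lapply(specs, as.numeric))
  out <- endmember_set(M, labels = paste0("endmember_", seq_len(n)))
  attr(out, "npeaks") <- vapply(specs, attr, integer(1), "npeaks")
  attr(out, "nsmall") <- vapply(specs, attr, integer(1), "nsmall")
  attr(out, "peaks") <- do.call(rbind, lapply(specs, attr, "peaks"))
  out
}

#' Abundance scene parameters
#'
#' @param kind `"chessboard"`, `"gaussian"` or `"dirichlet"`.
#' @param H,W Scene height and width in pixels (default 100 x 100, i.e.
#'   10,000 spectra per scene).
#' @param patch Chessboard patch edge in pixels (default 20); must divide
#'   both `H` and `W`.
#' @param gaussian_sigma Spatial spread (pixels) of the Gaussian bumps;
#'   `NULL` (default) uses `H / n`.
#' @param dirichlet_alpha Dirichlet concentration; a scalar is recycled to
#'   all `n` components (default 1, uniform on the simplex).
#' @param require_all Chessboard only: redraw the patch assignment until all
#'   `n` endmembers appear at least once (the number of draws used is
#'   recorded on the result). Default `FALSE`.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(kind = c("chessboard", "gaussian", "dirichlet"),
                         H = 100L, W = 100L, patch = 20L,
                         gaussian_sigma = NULL, dirichlet_alpha = 1,
                         require_all = FALSE) {
  kind <- match.arg(kind)
  H <- as.integer(H); W <- as.integer(W); patch <- as.integer(patch)
  if (H < 1 || W < 1) rmx_abort("Scene dims must be >= 1.", "ramanmix_error_param")
  if (kind == "chessboard" && (H %% patch != 0 || W %% patch != 0)) {
    rmx_abort(sprintf("Chessboard patch %d must divide H = %d and W = %d.",
                      patch, H, W), "ramanmix_error_param")
  }
  structure(as.list(environment()), class = "scene_params")
}

#' Generate a fractional-abundance scene
#'
#' Builds an `H x W` scene of fractional abundances over `n` endmembers.
#' All three scene kinds satisfy ANC and ASC exactly by construction:
#'
#' * `chessboard` — the scene is tiled with `patch x patch` square blocks,
#'   each assigned one endmember uniformly at random; every pixel in a block
#'   is the same one-hot vector.
#' * `gaussian` — `n` isotropic 2D Gaussian bumps centered at equally spaced
#'   points along the main diagonal; each pixel's vector of bump values is
#'   normalized to sum to one, giving smoothly overlapping species.
#' * `dirichlet` — every pixel i.i.d. from an `n`-dimensional Dirichlet
#'   distribution: a highly mixed scene with no pure pixels.
#'
#' Pixels are stored row-major (row by row from the top-left).
#'
#' @param params A [scene_params()] object.
#' @param n Number of endmembers.
#' @return An [abundance_map()] with `scene_shape = c(H, W)`.
#' @export
make_scene <- function(params = scene_params(), n = 5L) {
  stopifnot(inherits(params, "scene_params"), n >= 1)
  H <- params$H; W <- params$W
  A <- switch(params$kind,
    chessboard = {
      ph <- H / params$patch; pw <- W / params$patch
      draws <- 0L
      repeat {
        assign <- matrix(sample.int(n, ph * pw, replace = TRUE), ph, pw)
        draws <- draws + 1L
        if (!params$require_all || length(unique(as.vector(assign))) == n) break
      }
      # expand patch assignment to pixel grid, then one-hot encode
      pix <- assign[rep(seq_len(ph), each = params$patch),
                    rep(seq_len(pw), each = params$patch), drop = FALSE]
      A <- matrix(0, H * W, n)
      A[cbind(seq_len(H * W), as.vector(t(pix)))] <- 1
      attr(A, "scene_draws") <- draws
      A
    },
    gaussian = {
      sigma <- params$gaussian_sigma %||% (H / n)
      centers_r <- seq(0.5, H - 0.5, length.out = n + 2)[2:(n + 1)]
      centers_c <- seq(0.5, W - 0.5, length.out = n + 2)[2:(n + 1)]
      rows <- rep(seq_len(H), each = W) - 0.5
      cols <- rep(seq_len(W), times = H) - 0.5
      A <- vapply(seq_len(n), function(k) {
        exp(-((rows - centers_r[k])^2 + (cols - centers_c[k])^2) / (2 * sigma^2))
      }, numeric(H * W))
      A / rowSums(A)
    },
    dirichlet = {
      alpha <- rep_len(params$dirichlet_alpha, n)
      G <- matrix(rgamma(H * W * n, shape = rep(alpha, each = H * W)), H * W, n)
      G / rowSums(G)
    }
  )
  draws <- attr(A, "scene_draws")
  attr(A, "scene_draws") <- NULL
  out <- abundance_map(A, anc = TRUE, asc = TRUE, scene_shape = c(H, W))
  if (!is.null(draws)) attr(out, "scene_draws") <- draws
  out
}

#' Mix endmembers and abundances into spectra
#'
#' Applies the linear mixing model `x = sum_k alpha_k m_k`, or the bilinear
#' Fan model which adds all ordered pairwise Hadamard interaction terms
#' `sum_k sum_{l != k} (alpha_k m_k) * (alpha_l m_l)`.
#'
#' @param M An [endmember_set()] (`n x b`).
#' @param A An [abundance_map()] (`N x n`).
#' @param model `"linear"` or `"fan"`.
#' @param axis Optional wavenumber axis for the result.
#' @return A [spectral_dataset()] of `N` mixed spectra, inheriting `A`'s
#'   scene geometry.
#' @export
mix_spectra <- function(M, A, model = c("linear", "fan"), axis = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(M, "endmember_set"), inherits(A, "abundance_map"))
  Msig <- M$signatures
  Av <- A$values
  if (ncol(Av) != nrow(Msig)) {
    rmx_abort(sprintf("Abundance columns (%d) must match endmember rows (%d).",
                      ncol(Av), nrow(Msig)), "ramanmix_error_dim")
  }
  X <- Av %*% Msig
  if (model == "fan") {
    # sum over ordered pairs (k,l), l != k, of (a_k m_k) .* (a_l m_l)
    # equals (X .* X) - sum_k a_k^2 (m_k .* m_k)
    X <- X + X * X - (Av * Av) %*% (Msig * Msig)
  }
  spectral_dataset(X, axis = axis %||% seq_len(ncol(Msig)),
                   scene_shape = A$scene_shape)
}

#' Artifact injection parameters
#'
#' Defaults are the experimental settings of the benchmark datasets:
#' dark-noise level `sigma_noise = 0.1`, baseline probability
#' `p_baseline = 0.25` with amplitude `h_baseline = 2`, spike probability
#' `p_spike = 0.1` with amplitude `h_spike = 5`.
#'
#' @param sigma_noise Standard deviation of the i.i.d. Gaussian dark noise
#'   added to every band.
#' @param p_baseline Probability a spectrum receives the arctan baseline
#'   `B_j = h_baseline * atan(pi * j / b)` (1-based band index `j`).
#' @param h_baseline Baseline amplitude.
#' @param p_spike Probability a spectrum receives one cosmic spike of
#'   magnitude `h_spike * U(0.75, 1.25)` at a band drawn uniformly from
#'   `{2, ..., b - 2}` (1-based).
#' @param h_spike Spike amplitude.
#' @return A list of class `artifact_params`.
#' @export
artifact_params <- function(sigma_noise = 0.1, p_baseline = 0.25,
                            h_baseline = 2, p_spike = 0.1, h_spike = 5) {
  stopifnot(sigma_noise >= 0,
            p_baseline >= 0, p_baseline <= 1,
            p_spike >= 0, p_spike <= 1)
  structure(as.list(environment()), class = "artifact_params")
}

#' Add Raman data artifacts to a dataset
#'
#' Per spectrum: adds i.i.d. Gaussian dark noise to every band; with
#' probability `p_baseline` adds the smooth arctan baseline; with probability
#' `p_spike` adds a single-band cosmic spike (see [artifact_params()]).
#'
#' @param d A [spectral_dataset()].
#' @param params An [artifact_params()] object.
#' @return The corrupted dataset, with a `flags` attribute: a tibble with one
#'   row per spectrum (`baseline_added`, `spike_added`, `spike_band`,
#'   `spike_height`).
#' @export
add_artifacts <- function(d, params = artifact_params()) {
  stopifnot(inherits(d, "spectral_dataset"), inherits(params, "artifact_params"))
  X <- d$intensities
  N <- nrow(X); b <- ncol(X)
  if (params$sigma_noise > 0) {
    X <- X + matrix(rnorm(N * b, 0, params$sigma_noise), N, b)
  }
  baseline_added <- runif(N) < params$p_baseline
  if (any(baseline_added)) {
    B <- params$h_baseline * atan(pi * seq_len(b) / b)
    X[baseline_added, ] <- X[baseline_added, , drop = FALSE] +
      matrix(B, sum(baseline_added), b, byrow = TRUE)
  }
  spike_added <- runif(N) < params$p_spike
  spike_band <- rep(NA_integer_, N)
  spike_height <- rep(NA_real_, N)
  if (any(spike_added)) {
    idx <- which(spike_added)
    spike_band[idx] <- sample(2:(b - 2), length(idx), replace = TRUE)
    spike_height[idx] <- params$h_spike * runif(length(idx), 0.75, 1.25)
    X[cbind(idx, spike_band[idx])] <- X[cbind(idx, spike_band[idx])] +
      spike_height[idx]
  }
  out <- spectral_dataset(X, d$axis, d$scene_shape)
  attr(out, "flags") <- tibble::tibble(
    baseline_added = baseline_added,
    spike_added = spike_added,
    spike_band = spike_band,
    spike_height = spike_height
  )
  out
}

scenario_spec <- function(scenario) {
  switch(scenario,
    ideal     = list(noisy = FALSE, model = "linear", artifacts = FALSE),
    artifacts = list(noisy = FALSE, model = "linear", artifacts = TRUE),
    realistic = list(noisy = TRUE,  model = "linear", artifacts = TRUE),
    bilinear  = list(noisy = TRUE,  model = "fan",    artifacts = TRUE),
    rmx_abort(sprintf("Unknown scenario '%s'.", scenario), "ramanmix_error_param")
  )
}

# derive independent per-stage child seeds (< 2^31) from one root seed
child_seed <- function(seed, stage) {
  stages <- c(endmembers = 1, scene = 2, artifacts = 3, model = 4, benchmark = 5)
  (as.double(seed) * 7919 + 104729 * stages[[stage]]) %% 2147483629
}

#' Generate a synthetic Raman mixture dataset with ground truth
#'
#' Composes the full generation pipeline: endmember sampling, abundance
#' scene, mixing, and artifact injection. The four mixture scenarios, in
#' increasing complexity, are:
#'
#' * `ideal` — clean endmembers, linear mixing, no artifacts;
#' * `artifacts` — clean endmembers, linear mixing, plus dark noise,
#'   baselines and cosmic spikes;
#' * `realistic` — noisy endmembers (extra small peaks), linear mixing, plus
#'   artifacts;
#' * `bilinear` — noisy endmembers mixed with the bilinear Fan model, plus
#'   artifacts. The Chessboard scene is rejected for this scenario: one-hot
#'   abundances annihilate every bilinear cross term, so no bilinear
#'   interaction would be present.
#'
#' One root `seed` is expanded into independent child streams for the
#' endmember, scene and artifact stages, so each stage is reproducible on its
#' own and the same endmembers can be reused across scenarios.
#'
#' @param scene Scene kind or a full [scene_params()] object.
#' @param scenario One of `"ideal"`, `"artifacts"`, `"realistic"`,
#'   `"bilinear"`.
#' @param n Number of endmembers (default 5).
#' @param b Number of bands (default 1000).
#' @param seed Root seed (integer).
#' @param scene_dims `c(H, W)` scene dimensions, used when `scene` is given
#'   as a kind name (default `c(100, 100)`, i.e. 10,000 spectra).
#' @param endmember_args,artifact_args Optional lists of overrides passed to
#'   [endmember_params()] / [artifact_params()].
#' @param require_all_endmembers Chessboard only: redraw the patch assignment
#'   until every endmember appears (used for benchmark fixtures).
#' @return A list of class `raman_simulation` with elements `dataset` (a
#'   [spectral_dataset()]) and `record` (the generation record: ground-truth
#'   `endmembers` and `abundances`, `mixture_model`, per-spectrum artifact
#'   `flags`, `scenario`, `seed`).
#' @export
#' @examples
#' sim <- generate_raman_dataset("chessboard", "ideal", b = 200, seed = 1,
#'                               scene_dims = c(20, 20))
#' sim$dataset
generate_raman_dataset <- function(scene = "chessboard",
                                   scenario = c("ideal", "artifacts",
                                                "realistic", "bilinear"),
                                   n = 5L, b = 1000L, seed = 1L,
                                   scene_dims = c(100L, 100L),
                                   endmember_args = list(),
                                   artifact_args = list(),
                                   require_all_endmembers = FALSE) {
  scenario <- match.arg(scenario)
  spec <- scenario_spec(scenario)
  if (!inherits(scene, "scene_params")) {
    scene <- scene_params(scene, H = scene_dims[1], W = scene_dims[2],
                          require_all = require_all_endmembers)
  }
  if (scenario == "bilinear" && scene$kind == "chessboard") {
    rmx_abort(paste("The bilinear scenario is not defined on the Chessboard",
                    "scene: one-hot abundances cancel all bilinear cross",
                    "terms, so the mixture would be purely linear."),
              "ramanmix_error_param")
  }
  ep <- do.call(endmember_params,
                c(list(b = b, noisy = spec$noisy), endmember_args))

  set.seed(child_seed(seed, "endmembers"))
  M <- sample_endmembers(n, ep)

  set.seed(child_seed(seed, "scene"))
  A <- make_scene(scene, n)

  d <- mix_spectra(M, A, model = spec$model)

  flags <- tibble::tibble(
    baseline_added = rep(FALSE, nrow(d$intensities)),
    spike_added = rep(FALSE, nrow(d$intensities)),
    spike_band = rep(NA_integer_, nrow(d$intensities)),
    spike_height = rep(NA_real_, nrow(d$intensities))
  )
  if (spec$artifacts) {
    ap <- do.call(artifact_params, artifact_args)
    set.seed(child_seed(seed, "artifacts"))
    d <- add_artifacts(d, ap)
    flags <- attr(d, "flags")
    attr(d, "flags") <- NULL
  }

  record <- structure(
    list(endmembers = M, abundances = A, mixture_model = spec$model,
         flags = flags, scenario = scenario, scene_kind = scene$kind,
         seed = seed,
         scene_draws = attr(A, "scene_draws") %||% 1L),
    class = "generation_record"
  )
  structure(list(dataset = d, record = record), class = "raman_simulation")
}

#' @exportS3Method base::print
print.raman_simulation <- function(x, ...) {
  cat(sprintf("<raman_simulation> scenario '%s', scene '%s', seed %s\n",
              x$record$scenario, x$record$scene_kind, format(x$record$seed)))
  print(x$dataset)
  invisible(x)
}
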