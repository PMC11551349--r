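# Unified unmixing front end shared by the autoencoder and classical
# backends, plus the benchmark grid and the runtime-profiling harness.

AE_METHODS <- c("dense", "deep_dense", "conv", "transformer", "conv_transformer")
CLASSICAL_METHODS <- c("vca", "nfindr")

#' Unmix a spectral dataset
#'
#' Common entry point for all unmixing backends. Autoencoder methods train
#' a model on the dataset and read endmembers off the decoder and abundances
#' off the encoder; classical methods extract endmembers geometrically
#' (VCA or N-FINDR) and then estimate abundances by constrained least
#' squares (FCLS by default, NNLS with `abundance = "nnls"`).
#'
#' @param d A [spectral_dataset()].
#' @param method One of `"dense"`, `"deep_dense"`, `"conv"`,
#'   `"transformer"`, `"conv_transformer"`, `"vca"`, `"nfindr"`.
#' @param n_endmembers Number of endmembers to extract.
#' @param decoder AE methods: `"linear"` or `"fan"`.
#' @param asc Enforce sum-to-one abundances (AE latent softmax / FCLS).
#'   With `asc = FALSE` AE models use the soft-rectified tanh and classical
#'   methods use NNLS.
#' @param abundance Classical methods: `"fcls"` or `"nnls"` (overrides
#'   `asc`).
#' @param epochs,learning_rate,batch_size,loss,lambda AE training settings
#'   (see [training_config()]).
#' @param seed Seed for the method's randomness (AE initialization and
#'   shuffling, VCA directions, N-FINDR initialization).
#' @return A list of class `unmixing_result`: `endmembers`
#'   ([endmember_set()]), `abundances` ([abundance_map()]), `method`,
#'   `seed`, `config` (method parameters), and for AE methods the full
#'   `fit`.
#' @export
#' @examples
#' sim <- generate_raman_dataset("chessboard", "ideal", b = 120, seed = 7,
#'                               scene_dims = c(20, 20))
#' res <- unmix(sim$dataset, "vca", n_endmembers = 5, seed = 1)
#' evaluate_unmixing(res, sim$record)
unmix <- function(d, method = c(AE_METHODS, CLASSICAL_METHODS),
                  n_endmembers, decoder = c("linear", "fan"), asc = TRUE,
                  abundance = NULL, epochs = 10L, learning_rate = 0.001,
                  batch_size = 64L, loss = "sad", lambda = 1000,
                  seed = 1L) {
  method <- match.arg(method)
  decoder <- match.arg(decoder)
  stopifnot(inherits(d, "spectral_dataset"), n_endmembers >= 1)
  if (method %in% AE_METHODS) {
    model <- ae_model(b = ncol(d$intensities), m = n_endmembers,
                      encoder = method, decoder = decoder, asc = asc)
    cfg <- training_config(epochs = epochs, learning_rate = learning_rate,
                           batch_size = batch_size, loss = loss,
                           lambda = lambda, seed = seed)
    fit <- fit_autoencoder(model, d, cfg)
    out <- list(endmembers = extract_endmembers(fit),
                abundances = infer_abundances(fit, d),
                method = method, seed = seed,
                config = list(decoder = decoder, asc = asc, epochs = epochs,
                              learning_rate = learning_rate,
                              batch_size = batch_size, loss = loss,
                              lambda = lambda),
                fit = fit)
  } else {
    abundance <- abundance %||% if (asc) "fcls" else "nnls"
    M <- if (method == "vca") vca(d, n_endmembers, seed)
         else nfindr(d, n_endmembers, seed)
    A <- if (abundance == "fcls") fcls_abundance(M, d) else nnls_abundance(M, d)
    out <- list(endmembers = M, abundances = A,
                method = paste0(method, "_", abundance), seed = seed,
                config = list(abundance = abundance))
  }
  structure(out, class = "unmixing_result")
}

#' @exportS3Method base::print
print.unmixing_result <- function(x, ...) {
  cat(sprintf("<unmixing_result> method '%s', %d endmembers, %d spectra\n",
              x$method, nrow(x$endmembers$signatures), nrow(x$abundances$values)))
  invisible(x)
}

#' Benchmark grid configuration
#'
#' Describes the benchmark of unmixing methods over the 11 synthetic dataset
#' variants (4 mixture scenarios x 3 abundance scenes, minus the undefined
#' bilinear Chessboard combination). The full-scale grid mirrors the
#' benchmark study: 100 x 100 scenes, 1000 bands, 5 dataset seeds x 5 model
#' seeds; the reduced scale (default) shrinks scenes and replicates while
#' preserving the grid structure. Dataset and model seeds are shared across
#' mixture scenarios so cells are directly comparable.
#'
#' @param scale `"reduced"` or `"full"`; presets for the arguments below.
#' @param methods Character vector of [unmix()] methods.
#' @param scene_dims,b Scene size and band count per dataset.
#' @param dataset_seeds,model_seeds Integer vectors of replicate seeds.
#' @param epochs AE training epochs.
#' @param m_ideal,m_other AE latent dimension for the ideal scenario (5) and
#'   for scenarios with artifacts (6); classical methods always extract
#'   `n_true` endmembers.
#' @param n,patch Number of ground-truth endmembers and chessboard patch
#'   size.
#' @return A list of class `benchmark_grid`.
#' @export
benchmark_grid <- function(scale = c("reduced", "full"),
                           methods = c("nfindr", "vca", "dense", "conv",
                                       "transformer", "conv_transformer"),
                           scene_dims = NULL, b = NULL,
                           dataset_seeds = NULL, model_seeds = NULL,
                           epochs = 10L, m_ideal = 5L, m_other = 6L,
                           n = 5L, patch = NULL) {
  scale <- match.arg(scale)
  if (scale == "full") {
    scene_dims <- scene_dims %||% c(100L, 100L)
    b <- b %||% 1000L
    dataset_seeds <- dataset_seeds %||% 1:5
    model_seeds <- model_seeds %||% 1:5
  } else {
    scene_dims <- scene_dims %||% c(50L, 50L)
    b <- b %||% 1000L
    dataset_seeds <- dataset_seeds %||% 1:2
    model_seeds <- model_seeds %||% 1:2
  }
  patch <- patch %||% (scene_dims[1] %/% 5)
  structure(list(scale = scale, methods = methods, scene_dims = scene_dims,
                 b = b, dataset_seeds = dataset_seeds,
                 model_seeds = model_seeds, epochs = epochs,
                 m_ideal = m_ideal, m_other = m_other, n = n, patch = patch),
            class = "benchmark_grid")
}

benchmark_variants <- function() {
  v <- expand.grid(scenario = c("ideal", "artifacts", "realistic", "bilinear"),
                   scene = c("chessboard", "gaussian", "dirichlet"),
                   stringsAsFactors = FALSE)
  v[!(v$scenario == "bilinear" & v$scene == "chessboard"), ]
}

#' Run the benchmark grid
#'
#' Generates every dataset variant for every dataset seed, runs every method
#' for every model seed, Hungarian-matches endmembers to the ground truth,
#' and reports matched mean SAD and abundance MSE per cell. AE methods use a
#' linear decoder on linear variants and the bilinear Fan decoder on the
#' bilinear scenario, with latent dimension `m_ideal` on the ideal scenario
#' and `m_other` elsewhere. A method failure is recorded in the `error`
#' column and the grid continues.
#'
#' @param grid A [benchmark_grid()].
#' @param verbose Print one line per completed cell.
#' @return A tibble with one row per (scenario, scene, dataset_seed, method,
#'   model_seed): `mean_sad` (mean over matched endmembers, radians),
#'   `abundance_mse` (mean over spectra), `m`, `seconds`, `error`.
#' @export
run_benchmark <- function(grid = benchmark_grid(), verbose = FALSE) {
  stopifnot(inherits(grid, "benchmark_grid"))
  variants <- benchmark_variants()
  rows <- list()
  for (vi in seq_len(nrow(variants))) {
    scenario <- variants$scenario[vi]; scene <- variants$scene[vi]
    for (ds in grid$dataset_seeds) {
      sp <- scene_params(scene, H = grid$scene_dims[1], W = grid$scene_dims[2],
                         patch = grid$patch,
                         require_all = scene == "chessboard")
      sim <- generate_raman_dataset(sp, scenario, n = grid$n, b = grid$b,
                                    seed = ds)
      m_ae <- if (scenario == "ideal") grid$m_ideal else grid$m_other
      dec <- if (scenario == "bilinear") "fan" else "linear"
      for (method in grid$methods) {
        is_ae <- method %in% AE_METHODS
        for (ms in grid$model_seeds) {
          t0 <- proc.time()[["elapsed"]]
          cell <- tryCatch({
            res <- if (is_ae) {
              unmix(sim$dataset, method, n_endmembers = m_ae, decoder = dec,
                    asc = TRUE, epochs = grid$epochs, seed = ms)
            } else {
              unmix(sim$dataset, method, n_endmembers = grid$n,
                    abundance = "fcls", seed = ms)
            }
            ev <- evaluate_unmixing(res, sim$record)
            list(sad = ev$mean_sad, mse = ev$abundance_mse, err = NA_character_)
          }, error = function(e) {
            list(sad = NA_real_, mse = NA_real_, err = conditionMessage(e))
          })
          el <- proc.time()[["elapsed"]] - t0
          rows[[length(rows) + 1L]] <- tibble::tibble(
            scenario = scenario, scene = scene, dataset_seed = ds,
            method = if (is_ae) method else paste0(method, "_fcls"),
            model_seed = ms, m = if (is_ae) m_ae else grid$n,
            mean_sad = cell$sad, abundance_mse = cell$mse,
            seconds = el, error = cell$err)
          if (verbose) {
            cat(sprintf("[%s/%s seed %d] %s (seed %d): SAD %.4f MSE %.5f (%.1fs)\n",
                        scenario, scene, ds, method, ms,
                        cell$sad, cell$mse, el))
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Profile unmixing runtime versus dataset size
#'
#' Times each method end to end (including autoencoder training, so AE and
#' classical costs are comparable) on ideal Chessboard datasets of
#' increasing size, with `n = 5` endmembers for all methods and
#' `repetitions` wall-time measurements per cell. Dataset generation and
#' I/O are excluded from the timings. CPU only.
#'
#' @param sizes Ascending vector of spectrum counts; each must be a perfect
#'   square (scenes are `sqrt(N) x sqrt(N)`).
#' @param methods Methods understood by [unmix()].
#' @param repetitions Timings per (method, size) cell (default 3).
#' @param b Bands per spectrum.
#' @param n Endmembers (fixed at 5 for all methods).
#' @param epochs AE training epochs.
#' @param seed Seed for dataset generation and the methods.
#' @return A tibble with one row per (method, size, repetition) and a
#'   `seconds` wall-time column.
#' @export
profile_runtime <- function(sizes, methods = c("dense", "vca", "nfindr"),
                            repetitions = 3L, b = 1000L, n = 5L,
                            epochs = 10L, seed = 1L) {
  stopifnot(all(diff(sizes) > 0) || length(sizes) == 1)
  rows <- list()
  for (N in sizes) {
    H <- as.integer(round(sqrt(N)))
    if (H * H != N) {
      rmx_abort(sprintf("Size %d is not a perfect square.", N),
                "ramanmix_error_param")
    }
    divisors <- which(H %% seq_len(H) == 0)
    patch <- max(divisors[divisors <= max(H %/% 5, 1)])
    sp <- scene_params("chessboard", H = H, W = H, patch = patch)
    sim <- generate_raman_dataset(sp, "ideal", n = n, b = b, seed = seed)
    for (method in methods) {
      for (rep in seq_len(repetitions)) {
        t0 <- proc.time()[["elapsed"]]
        invisible(unmix(sim$dataset, method, n_endmembers = n,
                        epochs = epochs, seed = seed + rep))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          method = method, n_spectra = as.integer(N), repetition = rep,
          seconds = proc.time()[["elapsed"]] - t0)
      }
    }
  }
  dplyr::bind_rows(rows)
}
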