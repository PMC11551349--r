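# ggplot2 visualization methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_raster geom_col
#'   facet_wrap labs scale_fill_viridis_c theme_minimal position_dodge
#'   geom_errorbar
#' @export
ggplot2::autoplot

#' Plot spectra from a dataset
#'
#' @param object A [spectral_dataset()].
#' @param which Row indices to draw (default: up to 5 spectra).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_dataset <- function(object, which = NULL, ...) {
  which <- which %||% seq_len(min(5, nrow(object$intensities)))
  df <- tibble::tibble(
    spectrum = factor(rep(which, each = length(object$axis))),
    wavenumber = rep(object$axis, times = length(which)),
    intensity = as.vector(t(object$intensities[which, , drop = FALSE]))
  )
  ggplot(df, aes(.data$wavenumber, .data$intensity, color = .data$spectrum)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Wavenumber (cm⁻¹)", y = "Intensity (a.u.)") +
    theme_minimal()
}

#' Plot endmember signatures
#'
#' @param object An [endmember_set()].
#' @param axis Optional wavenumber axis (defaults to band indices).
#' @param ... Unused.
#' @return A ggplot object with one facet per endmember.
#' @export
autoplot.endmember_set <- function(object, axis = NULL, ...) {
  M <- object$signatures
  axis <- axis %||% seq_len(ncol(M))
  labs_v <- rownames(M) %||% paste0("endmember_", seq_len(nrow(M)))
  df <- tibble::tibble(
    endmember = factor(rep(labs_v, each = ncol(M)), levels = labs_v),
    wavenumber = rep(axis, times = nrow(M)),
    intensity = as.vector(t(M))
  )
  ggplot(df, aes(.data$wavenumber, .data$intensity)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~endmember, scales = "free_y") +
    labs(x = "Wavenumber (cm⁻¹)", y = "Intensity (a.u.)") +
    theme_minimal()
}

#' Plot abundance maps as scene images
#'
#' Requires a 2D `scene_shape` (for volumetric maps, select a z-layer
#' first).
#'
#' @param object An [abundance_map()] with 2D scene geometry.
#' @param ... Unused.
#' @return A ggplot object, one raster facet per endmember.
#' @export
autoplot.abundance_map <- function(object, ...) {
  s <- object$scene_shape
  if (is.null(s) || length(s) != 2) {
    rmx_abort("Abundance plotting needs a 2D scene_shape; use reshape first.",
              "ramanmix_error_param")
  }
  A <- object$values
  n <- ncol(A)
  df <- tibble::tibble(
    endmember = factor(rep(paste0("endmember_", seq_len(n)), each = nrow(A))),
    row = rep(rep(seq_len(s[1]), each = s[2]), times = n),
    col = rep(rep(seq_len(s[2]), times = s[1]), times = n),
    abundance = as.vector(A)
  )
  ggplot(df, aes(.data$col, .data$row, fill = .data$abundance)) +
    geom_raster() +
    facet_wrap(~endmember) +
    scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    labs(x = NULL, y = NULL, fill = "abundance") +
    theme_minimal()
}

#' Plot an autoencoder training trace
#'
#' @param object An `ae_fit`.
#' @param ... Unused.
#' @return A ggplot object of per-epoch mean training loss.
#' @export
autoplot.ae_fit <- function(object, ...) {
  ggplot(tidy(object), aes(.data$epoch, .data$loss)) +
    geom_line() +
    labs(x = "Epoch", y = "Mean training loss") +
    theme_minimal()
}

#' Summarize benchmark results as a bar chart
#'
#' Aggregates a [run_benchmark()] table to mean +/- sd per method and
#' dataset variant for the chosen metric.
#'
#' @param results Tibble from [run_benchmark()].
#' @param metric `"mean_sad"` or `"abundance_mse"`.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, metric = c("mean_sad", "abundance_mse")) {
  metric <- match.arg(metric)
  df <- results |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$scenario, .data$scene, .data$method) |>
    dplyr::summarise(mean = mean(.data[[metric]]),
                     sd = sd(.data[[metric]]), .groups = "drop")
  ggplot(df, aes(.data$method, .data$mean, fill = .data$method)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.3) +
    facet_wrap(~scenario + scene) +
    labs(y = metric, x = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
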