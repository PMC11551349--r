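#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rbeta rgamma median mad sd prcomp quantile
#' @importFrom utils head tail
NULL

rmx_abort <- function(message, class, ...) {
  abort(message, class = c(class, "ramanmix_error"), ...)
}

#' Spectral dataset container
#'
#' Bundles an `N x b` matrix of Raman intensities with its wavenumber axis
#' and, optionally, the spatial geometry of the scene the spectra were
#' rastered from. Intensities are arbitrary units and may be negative
#' (dark noise and baseline subtraction both push bands below zero), but must
#' be finite. The axis must be strictly increasing with at least two bands.
#'
#' @param intensities Numeric matrix, one spectrum per row (`N x b`).
#'   A single spectrum may be given as a vector.
#' @param axis Numeric vector of `b` strictly increasing wavenumber positions
#'   (cm^-1). Defaults to band indices `1:b`.
#' @param scene_shape Optional integer vector `c(H, W)` or `c(H, W, Z)` with
#'   `H * W * Z == N`. Pixels are stored row-major (row by row, origin
#'   top-left) with z-layers outermost.
#' @return An object of class `spectral_dataset`.
#' @seealso [validate_dataset()], [reshape_scene()], [save_dataset()]
#' @export
#' @examples
#' d <- spectral_dataset(matrix(runif(20), 4, 5))
#' d
spectral_dataset <- function(intensities, axis = NULL, scene_shape = NULL) {
  if (is.vector(intensities) && is.numeric(intensities)) {
    intensities <- matrix(intensities, nrow = 1)
  }
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    rmx_abort("`intensities` must be a numeric matrix (N spectra x b bands).",
              "ramanmix_error_type")
  }
  storage.mode(intensities) <- "double"
  if (is.null(axis)) axis <- seq_len(ncol(intensities))
  axis <- as.double(axis)
  if (!is.null(scene_shape)) scene_shape <- as.integer(scene_shape)
  d <- structure(
    list(intensities = intensities, axis = axis, scene_shape = scene_shape),
    class = "spectral_dataset"
  )
  v <- validate_dataset(d)
  if (length(v) > 0) {
    rmx_abort(paste0("Invalid spectral_dataset:\n", paste("-", v, collapse = "\n")),
              "ramanmix_error_invalid")
  }
  d
}

#' @exportS3Method base::print
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d bands, axis %.6g..%.6g cm^-1",
              nrow(x$intensities), ncol(x$intensities),
              x$axis[1], x$axis[length(x$axis)]))
  if (!is.null(x$scene_shape)) {
    cat(sprintf(", scene %s", paste(x$scene_shape, collapse = "x")))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$intensities)

#' Endmember set
#'
#' An `n x b` nonnegative matrix whose rows are the Raman signatures of pure
#' chemical species (endmembers). Rows may carry names. Stored row-major;
#' interfaces that follow the `b x n` column convention of the linear mixing
#' model (for example decoder weight matrices) transpose at the boundary.
#'
#' @param signatures Numeric matrix (`n x b`), or a vector for `n = 1`.
#' @param labels Optional character vector of endmember names.
#' @return An object of class `endmember_set`.
#' @export
endmember_set <- function(signatures, labels = NULL) {
  if (is.vector(signatures) && is.numeric(signatures)) {
    signatures <- matrix(signatures, nrow = 1)
  }
  if (!is.matrix(signatures) || !is.numeric(signatures)) {
    rmx_abort("`signatures` must be a numeric matrix (n endmembers x b bands).",
              "ramanmix_error_type")
  }
  storage.mode(signatures) <- "double"
  if (any(!is.finite(signatures))) {
    rmx_abort("Endmember signatures must be finite.", "ramanmix_error_invalid")
  }
  if (any(signatures < 0)) {
    rmx_abort("Endmember signatures must be nonnegative.", "ramanmix_error_invalid")
  }
  if (any(rowSums(abs(signatures)) == 0)) {
    rmx_abort("Endmember set contains an all-zero signature.", "ramanmix_error_invalid")
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(signatures))
    rownames(signatures) <- labels
  }
  structure(list(signatures = signatures, labels = labels),
            class = "endmember_set")
}

#' @exportS3Method base::print
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> %d endmembers x %d bands\n",
              nrow(x$signatures), ncol(x$signatures)))
  invisible(x)
}

#' Fractional-abundance map
#'
#' An `N x n` matrix of fractional abundances, one row per spectrum/pixel.
#' The abundance nonnegativity constraint (ANC, all entries >= 0) and the
#' sum-to-one constraint (ASC, rows sum to 1 within `1e-6`) are carried as
#' flags and enforced at construction when set.
#'
#' @param values Numeric matrix (`N x n`), or a vector for a single row.
#' @param anc,asc Logical; which abundance constraints the map claims.
#' @param scene_shape Optional scene geometry, as in [spectral_dataset()].
#' @return An object of class `abundance_map`.
#' @export
abundance_map <- function(values, anc = TRUE, asc = TRUE, scene_shape = NULL) {
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !is.numeric(values)) {
    rmx_abort("`values` must be a numeric matrix (N x n).", "ramanmix_error_type")
  }
  storage.mode(values) <- "double"
  if (anc && any(values < 0)) {
    rmx_abort("ANC violated: negative abundance entries.", "ramanmix_error_invalid")
  }
  if (asc && any(abs(rowSums(values) - 1) > 1e-6)) {
    rmx_abort("ASC violated: abundance rows must sum to 1 within 1e-6.",
              "ramanmix_error_invalid")
  }
  if (!is.null(scene_shape)) {
    scene_shape <- as.integer(scene_shape)
    if (prod(scene_shape) != nrow(values)) {
      rmx_abort("scene_shape product must equal the number of abundance rows.",
                "ramanmix_error_dim")
    }
  }
  structure(list(values = values, anc = anc, asc = asc,
                 scene_shape = scene_shape),
            class = "abundance_map")
}

#' @exportS3Method base::print
print.abundance_map <- function(x, ...) {
  cat(sprintf("<abundance_map> %d pixels x %d endmembers (ANC=%s, ASC=%s)\n",
              nrow(x$values), ncol(x$values), x$anc, x$asc))
  invisible(x)
}

#' Validate a spectral dataset
#'
#' Checks every container invariant and reports violations instead of
#' raising: the axis is strictly increasing with at least two bands, its
#' length matches the intensity columns, all values are finite, and any
#' `scene_shape` multiplies out to the number of spectra.
#'
#' @param d A `spectral_dataset` (or a bare list with the same fields).
#' @return Character vector of human-readable violations; empty when the
#'   dataset is well formed. Never raises.
#' @export
#' @examples
#' d <- spectral_dataset(matrix(1:12, 3, 4))
#' validate_dataset(d)
validate_dataset <- function(d) {
  out <- character()
  x <- d$intensities
  axis <- d$axis
  if (!is.matrix(x) || !is.numeric(x)) {
    return("intensities: not a numeric matrix")
  }
  if (length(axis) < 2) {
    out <- c(out, sprintf("axis: needs at least 2 bands, has %d", length(axis)))
  }
  bad <- which(diff(axis) <= 0)
  if (length(bad) > 0) {
    out <- c(out, sprintf(
      "axis: not strictly increasing at position %d (%.6g >= %.6g)",
      bad[1], axis[bad[1]], axis[bad[1] + 1]))
  }
  if (ncol(x) != length(axis)) {
    out <- c(out, sprintf("axis: length %d does not match %d intensity columns",
                          length(axis), ncol(x)))
  }
  nf <- which(!is.finite(x))
  if (length(nf) > 0) {
    out <- c(out, sprintf("intensities: non-finite value at flat index %d", nf[1]))
  }
  if (!is.null(d$scene_shape)) {
    s <- d$scene_shape
    if (!length(s) %in% c(2L, 3L) || any(s < 1)) {
      out <- c(out, sprintf("scene_shape: must be (H,W) or (H,W,Z) of positives, got (%s)",
                            paste(s, collapse = ",")))
    } else if (prod(s) != nrow(x)) {
      out <- c(out, sprintf("scene_shape: product %d does not equal N = %d",
                            prod(s), nrow(x)))
    }
  }
  out
}

#' Attach or drop the scene geometry of a dataset
#'
#' Spectra are stored one per row regardless of geometry; `reshape_scene()`
#' only records how the rows tile a 2D (`H x W`) or volumetric (`H x W x Z`)
#' raster, in row-major order with z-layers outermost. Intensities are never
#' touched, so `reshape_scene(reshape_scene(d, s), NULL)` returns the flat
#' dataset bit-identically.
#'
#' @param d A `spectral_dataset`.
#' @param shape `c(H, W)`, `c(H, W, Z)`, or `NULL` to flatten.
#' @return The dataset with updated `scene_shape`.
#' @export
reshape_scene <- function(d, shape = NULL) {
  stopifnot(inherits(d, "spectral_dataset"))
  if (is.null(shape)) {
    d["scene_shape"] <- list(NULL)
    return(d)
  }
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 1)) {
    rmx_abort("`shape` must be (H, W) or (H, W, Z) of positive integers.",
              "ramanmix_error_dim")
  }
  if (prod(shape) != nrow(d$intensities)) {
    rmx_abort(sprintf("Scene shape (%s) multiplies to %d but the dataset has %d spectra.",
                      paste(shape, collapse = ", "), prod(shape), nrow(d$intensities)),
              "ramanmix_error_dim")
  }
  d$scene_shape <- shape
  d
}
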