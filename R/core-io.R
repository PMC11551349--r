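#' Save and load spectral datasets
#'
#' Two on-disk serializations are supported:
#'
#' * `"binary"` — an array container (RDS serialization of a named list of
#'   arrays: `intensities`, `axis`, and optionally `scene_shape`,
#'   `endmembers`, `abundances`, `artifact_flags`). Round-trips are
#'   bit-exact.
#' * `"text"` — a delimited table whose first row is the wavenumber axis and
#'   whose subsequent rows are spectra, written with 17 significant digits
#'   (round-trips to >= 12 significant digits). Scene geometry travels in a
#'   flat key=value sidecar file `<path>.meta`.
#'
#' @param d A `spectral_dataset`.
#' @param path Output/input file path.
#' @param format `"binary"` or `"text"`; `load_dataset()` infers it from the
#'   file when not given.
#' @param extra Optional named list of additional arrays stored alongside the
#'   dataset in the binary container (e.g. ground-truth endmembers).
#' @return `save_dataset()` returns `path` invisibly; `load_dataset()`
#'   returns a `spectral_dataset` (with any extra arrays attached as the
#'   attribute `"extra"`).
#' @export
save_dataset <- function(d, path, format = c("binary", "text"), extra = NULL) {
  stopifnot(inherits(d, "spectral_dataset"))
  format <- match.arg(format)
  if (format == "binary") {
    payload <- c(
      list(ramanmix_container = 1L,
           intensities = d$intensities,
           axis = d$axis),
      if (!is.null(d$scene_shape)) list(scene_shape = d$scene_shape),
      extra
    )
    saveRDS(payload, path, version = 3)
  } else {
    tab <- rbind(d$axis, d$intensities)
    data.table::fwrite(data.table::as.data.table(tab), path, sep = "\t",
                       col.names = FALSE)
    meta <- character()
    if (!is.null(d$scene_shape)) {
      meta <- c(meta, paste0("scene_shape=", paste(d$scene_shape, collapse = "x")))
    }
    if (length(meta) > 0) writeLines(meta, paste0(path, ".meta"))
  }
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path, format = NULL) {
  if (!file.exists(path)) {
    rmx_abort(sprintf("File not found: %s", path), "ramanmix_error_io")
  }
  if (is.null(format)) {
    format <- if (is_rds_file(path)) "binary" else "text"
  }
  if (format == "binary") {
    payload <- tryCatch(readRDS(path), error = function(e) {
      rmx_abort(sprintf("Not a readable binary dataset container: %s (%s)",
                        path, conditionMessage(e)), "ramanmix_error_format")
    })
    if (!is.list(payload) || is.null(payload$intensities) || is.null(payload$axis)) {
      rmx_abort(sprintf("Container %s lacks 'intensities'/'axis' arrays.", path),
                "ramanmix_error_format")
    }
    d <- spectral_dataset(payload$intensities, payload$axis, payload$scene_shape)
    extra <- payload[setdiff(names(payload),
                             c("ramanmix_container", "intensities", "axis", "scene_shape"))]
    if (length(extra) > 0) attr(d, "extra") <- extra
    d
  } else {
    tab <- tryCatch(
      as.matrix(data.table::fread(path, sep = "\t", header = FALSE)),
      error = function(e) {
        rmx_abort(sprintf("Cannot parse delimited dataset %s: %s",
                          path, conditionMessage(e)), "ramanmix_error_format")
      })
    if (nrow(tab) < 2) {
      rmx_abort(sprintf("Delimited dataset %s: need an axis row plus >= 1 spectrum (row 2 missing).",
                        path), "ramanmix_error_format")
    }
    if (any(!is.finite(tab))) {
      bad <- which(!is.finite(tab), arr.ind = TRUE)[1, ]
      rmx_abort(sprintf("Delimited dataset %s: non-numeric field at row %d, column %d (truncated file?).",
                        path, bad[1], bad[2]), "ramanmix_error_format")
    }
    scene_shape <- NULL
    metapath <- paste0(path, ".meta")
    if (file.exists(metapath)) {
      kv <- read_keyvalues(metapath)
      if (!is.null(kv$scene_shape)) {
        scene_shape <- as.integer(strsplit(kv$scene_shape, "x", fixed = TRUE)[[1]])
      }
    }
    spectral_dataset(tab[-1, , drop = FALSE], tab[1, ], scene_shape)
  }
}

is_rds_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2)
  # RDS v2/3 files are gzip- (1f 8b) or xz/none-compressed serializations;
  # uncompressed ones start with "X\n" (58 0a).
  length(magic) == 2 &&
    (identical(magic, as.raw(c(0x1f, 0x8b))) || identical(magic, as.raw(c(0x58, 0x0a))))
}

read_keyvalues <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(out) <- vapply(kv, function(p) trimws(p[[1]]), character(1))
  out
}

write_keyvalues <- function(x, path) {
  writeLines(paste0(names(x), "=", vapply(x, as.character, character(1))), path)
  invisible(path)
}
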