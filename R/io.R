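#' Save and load designed filters
#'
#' Taps are stored as a flat little-endian float64 binary file with a
#' JSON sidecar (`<path>.json`) recording the sampling rate and the
#' design specification, so a filter file is self-describing.
#'
#' @param fir A `fir_filter`.
#' @param path Output path for the binary tap array.
#' @export
write_taps <- function(fir, path) {
  stopifnot(inherits(fir, "fir_filter"))
  con <- file(path, "wb")
  writeBin(fir$taps, con, endian = "little")
  close(con)
  spec <- fir$spec
  meta <- list(n_taps = length(fir$taps), fs = fir$fs,
               group_delay_samples = fir$group_delay_samples)
  if (!is.null(spec))
    meta$spec <- list(band_edges = spec$band_edges, gains = spec$gains,
                      fs = spec$fs, spline_power = spec$spline_power)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_taps
#' @export
read_taps <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  taps <- readBin(con, "double", meta$n_taps, endian = "little")
  close(con)
  fir_filter(taps, meta$fs)
}

#' Save and load time-frequency results
#'
#' A `tf_result` is stored as a directory: the coefficient matrix as an
#' on-disk [array store][disk_store_create] (`coefs`, one row per
#' frequency) plus `meta.json` holding the axes and method metadata.
#'
#' @param result A `tf_result`.
#' @param path Directory to create.
#' @export
save_tf_result <- function(result, path) {
  stopifnot(inherits(result, "tf_result"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dtype <- if (is.complex(result$coefs)) "complex128" else "float64"
  st <- disk_store_create(file.path(path, "coefs"), dim(result$coefs), dtype)
  for (i in seq_len(nrow(result$coefs)))
    store_write(st, i, 1L, result$coefs[i, ])
  jsonlite::write_json(list(freqs_hz = result$freqs_hz,
                            times_s = result$times_s,
                            method = result$method),
                       file.path(path, "meta.json"), digits = NA)
  invisible(path)
}

#' @rdname save_tf_result
#' @export
load_tf_result <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  st <- disk_store_open(file.path(path, "coefs"))
  tf_result(as.matrix(st), meta$freqs_hz, meta$times_s, meta$method)
}
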