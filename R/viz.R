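#' Render a time-frequency matrix to a raster image
#'
#' Writes a PNG with time on the horizontal axis (left to right) and
#' frequency on the vertical axis (low at the bottom), magnitude mapped
#' through a perceptually uniform colormap. Wavelet-grid results keep
#' their row order, which is geometric in frequency; use
#' [tf_freq_ticks()] for axis annotation positions.
#'
#' @param result A `tf_result` (or `sst_result`, coerced via
#'   [as_tf_result()]).
#' @param scale `"linear"`, `"log"` (log10 of magnitude) or `"db"`
#'   (`20*log10`). Log scales clip at -120 dB below the maximum.
#' @param out_image_path Output PNG path.
#' @param colors Colormap (vector of colors).
#' @return The output path, invisibly.
#' @export
render_tf <- function(result, scale = c("linear", "log", "db"),
                      out_image_path,
                      colors = grDevices::hcl.colors(256, "viridis")) {
  scale <- match.arg(scale)
  if (inherits(result, "sst_result")) result <- as_tf_result(result)
  stopifnot(inherits(result, "tf_result"))
  m <- Mod(result$coefs)
  if (length(m) == 0L) stop("empty time-frequency matrix")
  m <- switch(scale,
              linear = m,
              log = log10(pmax(m, max(m) * 1e-6)),
              db = 20 * log10(pmax(m, max(m) * 1e-6)))
  rng <- range(m)
  idx <- if (rng[1L] == rng[2L]) {
    matrix(1L, nrow(m), ncol(m))
  } else {
    matrix(1L + as.integer((m - rng[1L]) / diff(rng) * (length(colors) - 1L)),
           nrow(m), ncol(m))
  }
  rgb <- grDevices::col2rgb(colors) / 255
  # image rows run top-to-bottom; flip so high frequencies sit on top
  flip <- nrow(idx):1
  arr <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (k in 1:3) arr[, , k] <- matrix(rgb[k, idx[flip, ]], nrow(m), ncol(m))
  png::writePNG(arr, out_image_path)
  invisible(out_image_path)
}

#' Frequency-axis tick positions for a time-frequency result
#'
#' For wavelet-based results (geometric frequency grids) ticks are
#' placed at octave steps from the lowest center frequency (each tick
#' `2x` the previous); for linear grids (spectrograms), at pretty linear
#' positions.
#'
#' @param result A `tf_result` or `sst_result`.
#' @return Numeric vector of tick frequencies in Hz (a subset of the
#'   result's frequency axis for geometric grids).
#' @export
tf_freq_ticks <- function(result) {
  freqs <- if (inherits(result, "sst_result")) result$bin_freqs_hz
           else result$freqs_hz
  method <- if (inherits(result, "sst_result")) "sst" else result$method
  if (method %in% c("cwt", "cwt_dt", "sst")) {
    n_oct <- floor(log2(max(freqs) / min(freqs)))
    min(freqs) * 2^(0:n_oct)
  } else {
    pretty(freqs)
  }
}
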