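#' Analytic signal of a real time series
#'
#' One-sided frequency-domain construction: the DFT of the input is
#' scaled by 1 at DC (and at Nyquist when the length is even), by 2 at
#' positive frequencies and by 0 at negative frequencies, then inverse
#' transformed. The real part of the result equals the input exactly and
#' its spectrum vanishes on strictly negative frequencies; modulus and
#' argument give instantaneous envelope and phase. The transform runs at
#' the exact data length for every N (odd lengths simply have no Nyquist
#' bin): padding to a convenient length and truncating back would break
#' the one-sided property, so it is deliberately avoided, at a
#' mixed-radix FFT cost for awkward (e.g. prime) lengths.
#'
#' @param x Real vector or `channels x samples` matrix.
#' @param fs Sampling rate in Hz (carried in the result).
#' @return An `analytic_result` with complex `z`, `envelope = Mod(z)`,
#'   wrapped `phase = Arg(z)` in `(-pi, pi]`, and `fs`. For matrix input
#'   each field is a matrix.
#' @export
analytic_signal <- function(x, fs) {
  if (is.complex(x)) stop("real input required")
  was_vector <- !is.matrix(x)
  xm <- as_channel_matrix(x)
  n <- ncol(xm)
  scale <- one_sided_scale(n)
  z <- t(apply(xm, 1L, function(row) ifft(stats::fft(row) * scale)))
  if (was_vector) z <- drop(z[1L, , drop = TRUE])
  structure(list(z = z, envelope = Mod(z), phase = Arg(z), fs = fs),
            class = "analytic_result")
}

one_sided_scale <- function(L) {
  s <- numeric(L)
  s[1L] <- 1
  if (L %% 2 == 0) {
    s[2:(L / 2)] <- 2
    s[L / 2 + 1L] <- 1
  } else {
    s[2:((L + 1) / 2)] <- 2
  }
  s
}

#' @export
print.analytic_result <- function(x, ...) {
  n <- if (is.matrix(x$z)) ncol(x$z) else length(x$z)
  cat("analytic_result:", n, "samples at", x$fs, "Hz\n")
  invisible(x)
}

#' Instantaneous envelope of a (band-limited) oscillation
#'
#' Optionally band-pass filters the input (delay-corrected FIR via the
#' blocked convolution engine), takes the analytic-signal magnitude, and
#' optionally smooths the result with a second delay-corrected FIR. The
#' default applies neither filter and is then identical to
#' `Mod(analytic_signal(x, fs)$z)`.
#'
#' @param x Real vector or `channels x samples` matrix.
#' @param fs Sampling rate in Hz.
#' @param band Optional [filter_spec()] (or `c(f_lo, f_hi)` pass band,
#'   expanded via [bandpass_spec()]) applied before the analytic signal.
#' @param smooth Optional `fir_filter` applied to the envelope.
#' @return Real envelope, same shape as `x`.
#' @export
signal_envelope <- function(x, fs, band = NULL, smooth = NULL) {
  x <- apply_band(x, fs, band)
  env <- analytic_signal(x, fs)$envelope
  if (!is.null(smooth))
    env <- filter_data_fir(env, smooth, ds = 1, correct_delay = TRUE)
  env
}

#' Instantaneous phase of a (band-limited) oscillation
#'
#' Argument of the analytic signal of the optionally band-pass filtered
#' input. The convention is cosine-referenced: phase 0 falls at local
#' maxima of the band-limited oscillation. Wrapped to `(-pi, pi]` by
#' default.
#'
#' @inheritParams signal_envelope
#' @param unwrap If `TRUE`, return the cumulative (unwrapped) phase.
#' @return Phase in radians, same shape as `x`.
#' @export
signal_phase <- function(x, fs, band = NULL, unwrap = FALSE) {
  x <- apply_band(x, fs, band)
  ph <- analytic_signal(x, fs)$phase
  if (unwrap) {
    ph <- if (is.matrix(ph)) t(apply(ph, 1L, signal::unwrap))
          else signal::unwrap(ph)
  }
  ph
}

apply_band <- function(x, fs, band) {
  if (is.null(band)) return(x)
  if (is.numeric(band) && length(band) == 2L)
    band <- bandpass_spec(band[1L], band[2L], fs)
  fir <- if (inherits(band, "fir_filter")) band else design_fir(band)
  filter_data_fir(x, fir, ds = 1, correct_delay = TRUE)
}
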