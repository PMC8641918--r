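#' Specify a piecewise-constant magnitude response
#'
#' A filter is described by its transition bands and the desired linear
#' gain of each flat band between them. Transition bands are pairs
#' `(f1, f2)` in Hz with `0 <= f1 < f2 <= fs/2`, strictly ordered and
#' non-overlapping; `gains` has one more entry than there are transition
#' bands. The roll-off inside each transition follows a p-fold spline
#' (see [lowpass_prototype()]); larger `spline_power` gives a smoother,
#' steeper-tailed transition.
#'
#' @param band_edges A list of `c(f1, f2)` pairs, or a 2-column matrix
#'   (one row per transition band), in Hz.
#' @param gains Desired linear gain per flat band (`length(band_edges)+1`),
#'   all `>= 0`.
#' @param fs Sampling rate in Hz.
#' @param spline_power Positive integer p controlling roll-off smoothness.
#' @param n_taps Odd positive integer, or `"auto"` to size the filter from
#'   the narrowest transition band via [estimate_taps()].
#' @return A `filter_spec`.
#' @export
filter_spec <- function(band_edges, gains, fs, spline_power = 2,
                        n_taps = "auto") {
  if (is.matrix(band_edges))
    band_edges <- lapply(seq_len(nrow(band_edges)), function(i) band_edges[i, ])
  if (length(band_edges) == 0L) stop("at least one transition band required")
  edges <- do.call(rbind, lapply(band_edges, function(b) {
    stopifnot(length(b) == 2L)
    as.numeric(b)
  }))
  if (any(edges[, 1L] < 0) || any(edges[, 2L] > fs / 2) ||
      any(edges[, 1L] >= edges[, 2L]))
    stop("each transition band needs 0 <= f1 < f2 <= fs/2")
  flat <- as.vector(t(edges))
  if (is.unsorted(flat, strictly = TRUE))
    stop("transition bands must be strictly ordered and non-overlapping")
  if (length(gains) != nrow(edges) + 1L)
    stop("gains must have one more entry than there are transition bands")
  if (any(gains < 0)) stop("gains must be nonnegative")
  stopifnot(spline_power >= 1)
  if (!identical(n_taps, "auto")) {
    n_taps <- as.integer(n_taps)
    if (n_taps %% 2L == 0L) stop("n_taps must be odd")
  }
  structure(list(band_edges = edges, gains = as.numeric(gains), fs = fs,
                 spline_power = as.integer(spline_power), n_taps = n_taps),
            class = "filter_spec")
}

#' Spline-transition low-pass prototype
#'
#' Closed-form linear-phase low-pass impulse response with transition band
#' exactly `[omega1_hz, omega2_hz]`. In radian frequency (`w = 2*pi*f/fs`),
#' with `w0 = (w1 + w2)/2` and `dw = w2 - w1`, the taps at offsets
#' `n = -(M-1)/2 ... (M-1)/2` are
#' `h(n) = sin(w0*n)/(pi*n) * (sin(dw*n/(2p)) / (dw*n/(2p)))^p`,
#' i.e. an ideal low-pass at the transition midpoint whose frequency
#' response is smoothed by the p-fold convolution of boxcars of total
#' width `dw`. The design is analytic: no linear system is solved, so it
#' cannot fail to converge, the transition edges are exact, and the gain
#' at the transition midpoint is exactly 1/2 (-6 dB). Removable
#' singularities at `n = 0` are replaced by their limits; `dw = 0`
#' degenerates to the ideal (sinc) low-pass.
#'
#' @param omega1_hz,omega2_hz Transition-band edges in Hz,
#'   `0 < omega1_hz <= omega2_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param p Spline power, integer `>= 1`.
#' @param n_taps Odd number of taps M.
#' @return Numeric vector of M taps (symmetric, linear phase).
#' @export
lowpass_prototype <- function(omega1_hz, omega2_hz, fs, p, n_taps) {
  stopifnot(omega1_hz > 0 || omega2_hz > 0, omega1_hz <= omega2_hz,
            omega2_hz < fs / 2 || omega1_hz == omega2_hz, p >= 1)
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) stop("n_taps must be odd")
  w0 <- pi * (omega1_hz + omega2_hz) / fs   # 2*pi*f0/fs with f0 = midpoint
  dw <- 2 * pi * (omega2_hz - omega1_hz) / fs
  half <- (n_taps - 1L) / 2L
  n <- seq.int(-half, half)
  main <- ifelse(n == 0, w0 / pi, sin(w0 * n) / (pi * n))
  if (dw == 0) return(main)
  xs <- dw * n / (2 * p)
  spline <- ifelse(n == 0, 1, (sin(xs) / xs))^p
  main * spline
}

#' Design a linear-phase multiband FIR filter
#'
#' Composes [lowpass_prototype()] filters into an arbitrary
#' piecewise-constant magnitude response by a telescoping sum: with
#' transition bands `T_1..T_K` and band gains `g_1..g_{K+1}`,
#' `h = sum_k (g_k - g_{k+1}) * LP_k + g_{K+1} * delta`, where `LP_k` is
#' the low-pass prototype with transition `T_k` and `delta` is the
#' centered unit impulse (the Nyquist-wide low-pass). Each prototype is
#' exactly linear phase and passes through half its gain step at its
#' transition midpoint, so the composition inherits both properties: the
#' magnitude at the midpoint of each transition band is the arithmetic
#' mean of the adjacent band gains (-6.02 dB for a 1 -> 0 transition).
#'
#' @param spec A [filter_spec()].
#' @return A `fir_filter` with fields `taps`, `fs`, `group_delay_samples`,
#'   and the originating `spec`.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  n_taps <- spec$n_taps
  if (identical(n_taps, "auto")) {
    widths <- spec$band_edges[, 2L] - spec$band_edges[, 1L]
    n_taps <- estimate_taps(min(widths), spec$fs, spec$spline_power)
  }
  h <- numeric(n_taps)
  g <- spec$gains
  K <- nrow(spec$band_edges)
  for (k in seq_len(K)) {
    step <- g[k] - g[k + 1L]
    if (step != 0)
      h <- h + step * lowpass_prototype(spec$band_edges[k, 1L],
                                        spec$band_edges[k, 2L],
                                        spec$fs, spec$spline_power, n_taps)
  }
  if (g[K + 1L] != 0)
    h[(n_taps + 1L) / 2L] <- h[(n_taps + 1L) / 2L] + g[K + 1L]
  fir_filter(h, spec$fs, spec)
}

fir_filter <- function(taps, fs, spec = NULL) {
  m <- length(taps)
  if (m %% 2L == 0L) stop("fir_filter requires an odd number of taps")
  structure(list(taps = as.numeric(taps), fs = fs,
                 group_delay_samples = (m - 1L) / 2L, spec = spec),
            class = "fir_filter")
}

#' Group delay of a linear-phase FIR filter
#' @param fir A `fir_filter`.
#' @return Delay in samples, `(M-1)/2` (an integer; M is forced odd).
#' @export
group_delay <- function(fir) fir$group_delay_samples

#' @export
print.fir_filter <- function(x, ...) {
  cat("fir_filter:", length(x$taps), "taps, fs =", x$fs,
      "Hz, group delay", x$group_delay_samples, "samples\n")
  invisible(x)
}

#' Estimate the number of taps for a target stop-band attenuation
#'
#' The prototype has no closed-form tap-count rule, so the count is found
#' by search: candidate (odd) lengths are doubled until a prototype with
#' the requested transition width, placed mid-band, achieves a measured
#' stop-band ripple of at most `-atten_db` dB (maximum `|H|` beyond half a
#' transition width past the upper edge, on a dense frequency grid), then
#' the smallest passing odd length is located by bisection. The result is
#' non-increasing in `transition_width_hz`.
#'
#' @param transition_width_hz Transition-band width in Hz
#'   (`0 < width < fs/4`).
#' @param fs Sampling rate in Hz.
#' @param p Spline power.
#' @param atten_db Required stop-band attenuation in (positive) dB.
#' @param max_taps Search cap; exceeding it is an error.
#' @return Odd integer tap count.
#' @export
estimate_taps <- function(transition_width_hz, fs, p = 2, atten_db = 60,
                          max_taps = 2^22) {
  stopifnot(transition_width_hz > 0, transition_width_hz < fs / 4)
  dw <- transition_width_hz
  f1 <- (fs / 2 - dw) / 2
  f2 <- f1 + dw
  ok <- function(m) {
    measured_stopband_db(lowpass_prototype(f1, f2, fs, p, m), fs, f2, dw) <=
      -atten_db
  }
  lo <- 1L            # last known-failing (or floor) odd length
  m <- 3L
  while (!ok(m)) {
    lo <- m
    m <- 2L * m - 1L  # stays odd
    if (m > max_taps)
      stop("attenuation of ", atten_db, " dB unreachable within ",
           max_taps, " taps")
  }
  hi <- m
  while (hi - lo > 2L) {
    mid <- lo + (hi - lo) %/% 2L
    if (mid %% 2L == 0L) mid <- mid + 1L
    if (mid >= hi) break
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

measured_stopband_db <- function(taps, fs, f2, dw) {
  nfft <- next_fast_len(max(4096L, 8L * length(taps)))
  H <- stats::fft(c(taps, numeric(nfft - length(taps))))
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  stop_bins <- freqs >= (f2 + dw / 2) & freqs <= fs / 2
  20 * log10(max(abs(H[stop_bins])))
}

#' Frequency response of an FIR filter
#'
#' Evaluates the transfer function `H(f) = sum_n h[n] exp(-2i*pi*f*n/fs)`
#' at arbitrary frequencies (not restricted to an FFT grid).
#'
#' @param fir A `fir_filter` (or bare numeric tap vector plus `fs`).
#' @param freqs_hz Frequencies in `[0, fs/2]`, Hz.
#' @param fs Sampling rate; taken from `fir` when it is a `fir_filter`.
#' @return Complex vector `H(freqs_hz)`.
#' @export
frequency_response <- function(fir, freqs_hz, fs = NULL) {
  if (inherits(fir, "fir_filter")) {
    taps <- fir$taps
    fs <- fir$fs
  } else {
    taps <- as.numeric(fir)
    if (is.null(fs)) stop("fs required when passing bare taps")
  }
  if (any(freqs_hz < 0) || any(freqs_hz > fs / 2))
    stop("frequencies must lie in [0, fs/2]")
  n <- seq_along(taps) - 1L
  vapply(freqs_hz, function(f) {
    sum(taps * exp(-2i * pi * f * n / fs))
  }, complex(1))
}

#' Convenience band-pass specification
#'
#' Builds a [filter_spec()] for a single pass band with symmetric
#' spline transitions of width `transition_hz` on each side.
#'
#' @param f_lo,f_hi Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @param transition_hz Transition-band width (default 25% of the pass
#'   band, capped so the lower transition stays above 0 Hz).
#' @inheritParams filter_spec
#' @export
bandpass_spec <- function(f_lo, f_hi, fs,
                          transition_hz = 0.25 * (f_hi - f_lo),
                          spline_power = 2, n_taps = "auto") {
  stopifnot(0 < f_lo, f_lo < f_hi, f_hi < fs / 2)
  tw <- min(transition_hz, f_lo * 0.99, (fs / 2 - f_hi) * 0.99)
  filter_spec(list(c(f_lo - tw, f_lo), c(f_hi, f_hi + tw)),
              gains = c(0, 1, 0), fs = fs,
              spline_power = spline_power, n_taps = n_taps)
}
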