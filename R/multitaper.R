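#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the DPSS taper family for data length `n` and smoothing
#' half-bandwidth `W` (Hz): the orthonormal sequences that maximize the
#' fraction of spectral energy inside `[-W, W]`. They are obtained as the
#' top eigenvectors of the symmetric tridiagonal matrix that commutes
#' with the concentration operator (solved with LAPACK `dstevr`, so
#' large `n` stays cheap); the concentration of each taper is then the
#' quadratic form of the sinc concentration kernel, evaluated via FFT
#' autocorrelation in O(n log n). Tapers are sign-fixed so that the taper
#' sum (or, when that is numerically zero, the first element of
#' appreciable size) is positive.
#'
#' The default taper count is `max(1, floor(2*n*W/fs) - 1)` (the Shannon
#' number minus one); requesting more produces poorly concentrated
#' tapers and a warning.
#'
#' @param n Data length in samples (`>= 2`).
#' @param half_bandwidth_hz One-sided smoothing bandwidth W in Hz,
#'   `0 < W < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param n_tapers Number of tapers L (default: Shannon heuristic).
#' @return A `taper_set`: `tapers` (L x n matrix, rows unit-energy and
#'   mutually orthogonal), `concentrations` (strictly decreasing, in
#'   (0, 1]), `n`, `half_bandwidth_hz`, `fs`.
#' @export
get_tapers <- function(n, half_bandwidth_hz, fs, n_tapers = NULL) {
  stopifnot(n >= 2, half_bandwidth_hz > 0)
  if (half_bandwidth_hz >= fs / 2)
    stop("half bandwidth must be below fs/2")
  w <- half_bandwidth_hz / fs
  shannon <- 2 * n * w
  if (is.null(n_tapers)) n_tapers <- max(1L, floor(shannon) - 1L)
  n_tapers <- as.integer(n_tapers)
  stopifnot(n_tapers >= 1L)
  if (n_tapers > shannon)
    warning("requesting ", n_tapers, " tapers with 2*n*W/fs = ",
            round(shannon, 2), "; extra tapers are poorly concentrated")
  i <- 0:(n - 1)
  dg <- (((n - 1) - 2 * i) / 2)^2 * cos(2 * pi * w)
  od <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  eig <- .Call(C_trideig_top, dg, od, n_tapers)
  # dstevr returns ascending; we want decreasing concentration order
  v <- eig$vectors[, rev(seq_len(n_tapers)), drop = FALSE]
  tapers <- t(v)
  for (l in seq_len(n_tapers)) {
    s <- sum(tapers[l, ])
    if (abs(s) < 1e-8) {
      big <- which(abs(tapers[l, ]) > 0.5 * max(abs(tapers[l, ])))[1L]
      s <- tapers[l, big]
    }
    if (s < 0) tapers[l, ] <- -tapers[l, ]
  }
  structure(list(tapers = tapers,
                 concentrations = dpss_concentrations(tapers, w),
                 n = n, half_bandwidth_hz = half_bandwidth_hz, fs = fs),
            class = "taper_set")
}

# lambda_l = sum_{d} r_l(d) * s(d), where r_l is the autocorrelation of
# taper l and s(d) = sin(2*pi*w*d)/(pi*d) (s(0) = 2w) is the band-limiting
# kernel; computed with one FFT per taper.
dpss_concentrations <- function(tapers, w) {
  n <- ncol(tapers)
  L <- next_fast_len(2 * n)
  d <- 1:(n - 1)
  s <- c(2 * w, sin(2 * pi * w * d) / (pi * d))
  apply(tapers, 1L, function(v) {
    V <- stats::fft(c(v, numeric(L - n)))
    r <- Re(ifft(V * Conj(V)))[seq_len(n)]  # r[1] = lag 0
    r[1L] * s[1L] + 2 * sum(r[-1L] * s[-1L])
  })
}

#' @export
print.taper_set <- function(x, ...) {
  cat("taper_set: ", nrow(x$tapers), " DPSS tapers, n = ", x$n,
      ", W = ", x$half_bandwidth_hz, " Hz (fs = ", x$fs, " Hz)\n",
      "concentrations: ", paste(signif(x$concentrations, 6), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Multitaper spectrum estimate
#'
#' Averages `L` statistically independent direct spectral estimates, one
#' per DPSS taper: `S_l(k) = (1/fs) |FFT(v_l * x)(k)|^2`, and
#' `S(k) = mean_l S_l(k)` (uniform weights). Output is one-sided: all
#' bins except DC and (for even `nfft`) Nyquist are doubled, so white
#' noise of variance `s^2` has flat level `2*s^2/fs` and total power
#' `sum(psd) * fs / nfft ~ s^2`.
#'
#' @param data Real 1-D signal, length `>= 8`.
#' @param half_bandwidth_hz Smoothing half-bandwidth W in Hz. Frequency
#'   features closer than `2W` are merged; larger W means lower variance.
#' @param fs Sampling rate in Hz.
#' @param nfft Transform length (default next 5-smooth `>= length(data)`).
#' @param n_tapers Taper count override (see [get_tapers()]).
#' @param tapers Optional precomputed `taper_set` (reused across calls).
#' @param detrend `"none"` (default) or `"mean"` (remove the mean first).
#' @return A `spectrum_result`: `freqs_hz`, `psd` (nonnegative),
#'   `n_tapers_used`, `nfft`.
#' @export
mtm_spectrum <- function(data, half_bandwidth_hz, fs, nfft = NULL,
                         n_tapers = NULL, tapers = NULL, detrend = "none") {
  if (is.complex(data)) stop("real input required")
  data <- as.numeric(data)
  n <- length(data)
  stopifnot(n >= 8)
  if (detrend == "mean") data <- data - mean(data)
  if (is.null(tapers))
    tapers <- get_tapers(n, half_bandwidth_hz, fs, n_tapers)
  stopifnot(ncol(tapers$tapers) == n)
  if (is.null(nfft)) nfft <- next_fast_len(n)
  L <- nrow(tapers$tapers)
  k_half <- floor(nfft / 2) + 1L
  acc <- numeric(k_half)
  for (l in seq_len(L)) {
    X <- stats::fft(c(tapers$tapers[l, ] * data, numeric(nfft - n)))
    acc <- acc + abs(X[seq_len(k_half)])^2 / fs
  }
  psd <- acc / L
  dbl <- rep(2, k_half)
  dbl[1L] <- 1
  if (nfft %% 2 == 0) dbl[k_half] <- 1
  structure(list(freqs_hz = (seq_len(k_half) - 1L) * fs / nfft,
                 psd = psd * dbl, n_tapers_used = L, nfft = nfft),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("spectrum_result:", length(x$freqs_hz), "bins up to",
      round(max(x$freqs_hz), 2), "Hz,", x$n_tapers_used, "tapers\n")
  invisible(x)
}

#' Multitaper spectrogram
#'
#' Slides a window of `nperseg` samples with hop `nperseg - noverlap`
#' and applies [mtm_spectrum()] to each window (one shared taper set).
#' Timestamps are window centers: `((nperseg-1)/2 + k*hop) / fs`. A
#' trailing partial window is dropped.
#'
#' @inheritParams mtm_spectrum
#' @param nperseg Window length in samples.
#' @param noverlap Samples shared by adjacent windows,
#'   `0 <= noverlap < nperseg`.
#' @return A `tf_result` with real `coefs` (`n_freqs x n_windows` PSD
#'   matrix), `freqs_hz`, `times_s`, and metadata.
#' @export
mtm_spectrogram <- function(data, half_bandwidth_hz, fs, nperseg, noverlap,
                            nfft = NULL, n_tapers = NULL, detrend = "none") {
  data <- as.numeric(data)
  n <- length(data)
  stopifnot(noverlap >= 0, noverlap < nperseg)
  if (nperseg > n) stop("nperseg exceeds the data length")
  hop <- nperseg - noverlap
  n_win <- 1L + floor((n - nperseg) / hop)
  tapers <- get_tapers(nperseg, half_bandwidth_hz, fs, n_tapers)
  if (is.null(nfft)) nfft <- next_fast_len(nperseg)
  cols <- lapply(seq_len(n_win) - 1L, function(k) {
    seg <- data[(k * hop + 1L):(k * hop + nperseg)]
    mtm_spectrum(seg, half_bandwidth_hz, fs, nfft = nfft,
                 tapers = tapers, detrend = detrend)$psd
  })
  freqs <- (seq_len(floor(nfft / 2) + 1L) - 1L) * fs / nfft
  tf_result(do.call(cbind, cols), freqs,
            ((nperseg - 1) / 2 + (seq_len(n_win) - 1L) * hop) / fs,
            method = "mtm_spectrogram",
            meta = list(half_bandwidth_hz = half_bandwidth_hz,
                        nperseg = nperseg, noverlap = noverlap,
                        n_tapers = nrow(tapers$tapers), fs = fs))
}

#' Time-frequency result container
#'
#' @param coefs `n_freqs x n_times` matrix (complex for CWT/SST, real
#'   PSD for spectrograms).
#' @param freqs_hz,times_s Axis vectors matching `coefs`.
#' @param method Tag identifying the producing method.
#' @param meta Parameter list carried for provenance/rendering.
#' @export
tf_result <- function(coefs, freqs_hz, times_s, method, meta = list()) {
  stopifnot(nrow(coefs) == length(freqs_hz), ncol(coefs) == length(times_s))
  structure(list(coefs = coefs, freqs_hz = freqs_hz, times_s = times_s,
                 method = method, meta = meta),
            class = "tf_result")
}

#' @export
print.tf_result <- function(x, ...) {
  cat("tf_result [", x$method, "]: ", nrow(x$coefs), " freqs x ",
      ncol(x$coefs), " times, ", round(min(x$freqs_hz), 3), "-",
      round(max(x$freqs_hz), 3), " Hz\n", sep = "")
  invisible(x)
}
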