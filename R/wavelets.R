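#' Analytic wavelet families
#'
#' Constructors for the three analytic mother wavelets, defined directly
#' in the frequency domain (zero for `omega <= 0`, so coefficients of
#' real signals carry meaningful instantaneous phase):
#'
#' * Morse: `Psi(a*w) = 2 (e*gamma/beta)^(beta/gamma) (a*w)^beta
#'   exp(-(a*w)^gamma)` for `w > 0`; peak radian frequency
#'   `(beta/gamma)^(1/gamma)`. `gamma` controls symmetry, `beta`
#'   time-bandwidth.
#' * Morlet: `Psi(a*w) = 2 exp(-(a*w - omega0)^2 / 2)` for `w > 0`; peak
#'   `omega0`. No admissibility correction term is applied.
#' * Bump: `Psi(a*w) = 2 exp(1 - 1/(1 - ((a*w - mu)/sigma)^2))` on
#'   `(mu - sigma)/a < w < (mu + sigma)/a`, else 0; peak `mu`. Compact
#'   frequency support of half-width `sigma`.
#'
#' All are normalized to peak value 2, so a unit-amplitude real tone at a
#' scale's center frequency yields CWT coefficients of magnitude ~1.
#'
#' @param gamma,beta Morse shape parameters (`> 0`); defaults (3, 20)
#'   give a symmetric, narrowband wavelet, `beta = 10` a more temporally
#'   compact one.
#' @param omega0 Morlet center radian frequency (`> 0`).
#' @param mu,sigma Bump center and half-width in radian frequency
#'   (`0 < sigma < mu`).
#' @return A `wavelet_spec`.
#' @name wavelet_families
NULL

#' @rdname wavelet_families
#' @export
morse_wavelet <- function(gamma = 3, beta = 20) {
  stopifnot(gamma > 0, beta > 0)
  structure(list(family = "morse", gamma = gamma, beta = beta),
            class = "wavelet_spec")
}

#' @rdname wavelet_families
#' @export
morlet_wavelet <- function(omega0 = 6) {
  stopifnot(omega0 > 0)
  structure(list(family = "morlet", omega0 = omega0),
            class = "wavelet_spec")
}

#' @rdname wavelet_families
#' @export
bump_wavelet <- function(mu = 5, sigma = 0.6) {
  stopifnot(mu > 0, sigma > 0, sigma < mu)
  structure(list(family = "bump", mu = mu, sigma = sigma),
            class = "wavelet_spec")
}

#' Peak radian frequency of a wavelet
#' @param spec A `wavelet_spec`.
#' @return The radian frequency at which the frequency-domain wavelet
#'   attains its maximum (used for the scale-to-frequency mapping).
#' @export
peak_omega <- function(spec) {
  switch(spec$family,
         morse = (spec$beta / spec$gamma)^(1 / spec$gamma),
         morlet = spec$omega0,
         bump = spec$mu)
}

#' Evaluate a wavelet in the frequency domain
#'
#' Returns `Psi(scale * omega)` for the given family; exactly 0 at
#' `omega <= 0` (analyticity) and outside the bump support.
#'
#' @param spec A `wavelet_spec`.
#' @param scale Positive scale a.
#' @param omega Radian frequencies (any sign).
#' @return Nonnegative real vector, peak value 2.
#' @export
wavelet_freq <- function(spec, scale, omega) {
  stopifnot(scale > 0)
  aw <- scale * omega
  out <- numeric(length(omega))
  pos <- omega > 0
  switch(spec$family,
    morse = {
      g <- spec$gamma; b <- spec$beta
      # log-space evaluation: (e*g/b)^(b/g) * aw^b can overflow separately
      lg <- (b / g) * (1 + log(g) - log(b)) + b * log(aw[pos]) - aw[pos]^g
      out[pos] <- 2 * exp(lg)
    },
    morlet = {
      out[pos] <- 2 * exp(-(aw[pos] - spec$omega0)^2 / 2)
    },
    bump = {
      u <- (aw - spec$mu) / spec$sigma
      inside <- pos & abs(u) < 1
      out[inside] <- 2 * exp(1 - 1 / (1 - u[inside]^2))
    })
  out
}

#' Logarithmic scale grid for the CWT
#'
#' Center frequencies `f_lo * 2^(k/V)` for
#' `k = 0 ... ceiling(V * log2(f_hi/f_lo)) - 1` (`V` voices per octave;
#' consecutive frequencies are in exact ratio `2^(1/V)`, and the count is
#' `ceiling(V * log2(f_hi/f_lo))` — e.g. 1-350 Hz at 10 voices gives 85
#' frequencies). Scales follow the peak-frequency mapping
#' `a = peak_omega(spec) * fs / (2*pi*f)`.
#'
#' @param f_lo_hz,f_hi_hz Frequency range, `0 < f_lo < f_hi <= fs/2`.
#' @param voices_per_octave Positive integer V.
#' @param spec A `wavelet_spec`.
#' @param fs Sampling rate in Hz.
#' @return A `scale_grid` with ascending `freqs_hz`, matching `scales`,
#'   `voices_per_octave`, `fs`.
#' @export
make_scale_grid <- function(f_lo_hz, f_hi_hz, voices_per_octave, spec, fs) {
  stopifnot(f_lo_hz > 0, f_hi_hz > f_lo_hz, f_hi_hz <= fs / 2,
            voices_per_octave >= 1)
  V <- as.integer(voices_per_octave)
  k <- seq_len(ceiling(V * log2(f_hi_hz / f_lo_hz))) - 1L
  freqs <- f_lo_hz * 2^(k / V)
  structure(list(freqs_hz = freqs,
                 scales = peak_omega(spec) * fs / (2 * pi * freqs),
                 voices_per_octave = V, fs = fs),
            class = "scale_grid")
}

#' @export
print.scale_grid <- function(x, ...) {
  cat("scale_grid:", length(x$freqs_hz), "frequencies,",
      round(min(x$freqs_hz), 4), "-", round(max(x$freqs_hz), 4), "Hz at",
      x$voices_per_octave, "voices/octave\n")
  invisible(x)
}

# Measured time support of a wavelet at one scale: half-width (samples)
# such that the l1 mass of |psi| outside it is <= tail_frac of the total
# (bounding the relative error of truncating the kernel to that window).
# psi is obtained by inverse transform of the frequency-domain form on a
# reference grid, grown until the window plus margin fits. Scales whose
# frequency response has not decayed at Nyquist have kernels with 1/t
# ringing and no usable compact support; they are reported as Inf and
# handled by a signal-length transform instead of block convolution.
wavelet_support <- function(spec, scale, fs, tail_frac = 1e-9) {
  if (wavelet_freq(spec, scale, pi) > 2e-12) return(Inf)
  L <- next_fast_len(max(1024, 8 * ceiling(scale)))
  repeat {
    w <- 2 * pi * grid_freqs(L) # rad/sample
    psi <- abs(ifft(wavelet_freq(spec, scale, w)))
    # center at index 1 (t = 0); fold to distances 0, 1, ..., L/2
    half <- L %/% 2
    mass <- psi[1L]
    tails <- psi[2:(half + 1L)] + psi[L:(L - half + 1L)]
    cum <- mass + cumsum(tails)
    tot <- cum[half]
    hw <- which(cum >= (1 - tail_frac) * tot)[1L]
    if (!is.na(hw) && hw <= L / 4) return(hw)
    if (L >= 2^21)
      stop("wavelet support exceeds the measurable range at scale ", scale)
    L <- next_fast_len(2 * L)
  }
}

# signed frequency fractions k/L for a length-L DFT grid
grid_freqs <- function(L) {
  k <- 0:(L - 1)
  ifelse(k <= L / 2, k, k - L) / L
}

#' Continuous wavelet transform of a real signal
#'
#' Computes, for each scale `a` of the grid, the inverse transform of
#' `X(w_k) * Conj(Psi(a * w_k))` — a pointwise product of discrete
#' Fourier transforms — so the wavelet is only ever sampled in the
#' frequency domain. A time-domain wavelet is never materialized on the
#' analysis path; this keeps coefficient rows numerically analytic even
#' for center frequencies near Nyquist, where a truncated time-domain
#' wavelet would leak onto negative frequencies.
#'
#' Boundary handling is periodic: the transform is an exact pointwise
#' product on the signal-length DFT grid, so the signal is implicitly
#' circular and edge samples within a wavelet support half-width of
#' either end mix information from both ends. Two execution paths
#' produce matching results (to ~1e-8 relative): `method = "full"` uses
#' one signal-length transform per scale; `method = "overlap_save"`
#' convolves blockwise with per-scale FFT lengths sized from each
#' wavelet's measured time support (reading the input with wraparound),
#' and is the out-of-core path: with `out` given, each scale's row is
#' written as it is produced and the full matrix is never held in
#' memory. Scales whose kernels have no usable compact support (center
#' frequency so close to Nyquist that the frequency response has not
#' decayed there) are computed by the signal-length transform inside
#' either path.
#'
#' @param data Real 1-D signal (or single-channel array store).
#' @param spec A `wavelet_spec` (default Morse gamma 3, beta 20).
#' @param grid A [make_scale_grid()] grid; frequencies above Nyquist are
#'   rejected.
#' @param fs Sampling rate in Hz.
#' @param method `"full"` or `"overlap_save"`.
#' @param out Optional preallocated output store, shape
#'   `(n_freqs, n_samples)`, complex dtype.
#' @param describe If `TRUE` return [dry_run()] sizing only.
#' @param n_workers Scales are independent work items; the result does
#'   not depend on the worker count.
#' @return A `tf_result` with complex `coefs` (`n_freqs x n_samples`),
#'   or the filled `out` store (invisibly), or a `dry_run_info`.
#' @export
cwt <- function(data, spec = morse_wavelet(), grid, fs,
                method = c("full", "overlap_save"), out = NULL,
                describe = FALSE, n_workers = 1L) {
  method <- match.arg(method)
  if (inherits(data, "array_store")) {
    d <- dim(data)
    stopifnot(d[1L] == 1L)
    n <- d[2L]
  } else {
    if (is.complex(data)) stop("real input required")
    data <- as.numeric(data)
    n <- length(data)
  }
  stopifnot(inherits(grid, "scale_grid"))
  if (max(grid$freqs_hz) > fs / 2)
    stop("grid contains frequencies above Nyquist")
  n_sc <- length(grid$scales)
  info <- dry_run_info(c(n_sc, n), "complex128", n_sc)
  if (describe) return(info)
  if (inherits(data, "array_store")) data <- store_read(data, 1L, 1L, n)
  user_out <- !is.null(out)
  if (user_out) {
    if (!all(dim(out) == info$out_shape) ||
        !grepl("^complex", store_dtype(out)))
      stop("out must be a complex store of shape (",
           paste(info$out_shape, collapse = ", "), ")")
  }
  hws <- vapply(grid$scales, function(a) wavelet_support(spec, a, fs),
                numeric(1))
  rows <- if (method == "full") {
    cwt_rows_full(data, spec, grid, hws, n_workers, fs)
  } else {
    cwt_rows_ols(data, spec, grid, hws, n_workers, fs)
  }
  if (user_out) {
    for (s in seq_len(n_sc)) store_write(out, s, 1L, rows[[s]])
    return(invisible(out))
  }
  tf_result(do.call(rbind, rows), grid$freqs_hz, (seq_len(n) - 1) / fs,
            method = "cwt",
            meta = list(spec = spec, grid = grid, fs = fs,
                        cwt_method = method))
}

# one exact signal-length transform per scale (periodic boundary; the
# coefficient row is one-sided on the length-n DFT grid by construction).
# deriv multiplies by j*omega (rad/s) to produce the time derivative of
# the coefficients with the same pipeline and boundary convention.
cwt_rows_full <- function(data, spec, grid, hws, n_workers, fs,
                          deriv = FALSE) {
  n <- length(data)
  X <- stats::fft(data)
  w <- 2 * pi * grid_freqs(n)
  mult <- if (deriv) 1i * w * fs else 1
  map_workers(seq_along(grid$scales), function(s) {
    ifft(X * wavelet_freq(spec, grid$scales[s], w) * mult)
  }, n_workers)
}

# blockwise overlap-save per scale with periodic (wraparound) input
# reads, matching the circular convolution of the full path; the wavelet
# is re-sampled on each scale's block-length frequency grid, never in
# the time domain. Scales without compact support (hw = Inf) and scales
# whose block would cover the signal anyway use the signal-length
# transform, which is then identical to the full path.
cwt_rows_ols <- function(data, spec, grid, hws, n_workers, fs,
                         deriv = FALSE) {
  n <- length(data)
  X <- NULL
  if (any(!is.finite(hws) | next_fast_len_v(4 * (2 * hws + 1)) >= n))
    X <- stats::fft(data)
  map_workers(seq_along(grid$scales), function(s) {
    hw <- hws[s]
    L <- if (is.finite(hw)) next_fast_len(max(4 * (2 * hw + 1), 256)) else Inf
    if (L >= n) {
      w <- 2 * pi * grid_freqs(n)
      Psi <- wavelet_freq(spec, grid$scales[s], w)
      if (deriv) Psi <- Psi * (1i * w * fs)
      return(ifft(X * Psi))
    }
    B <- L - 2 * hw                      # new output samples per block
    w <- 2 * pi * grid_freqs(L)
    Psi <- wavelet_freq(spec, grid$scales[s], w)
    if (deriv) Psi <- Psi * (1i * w * fs)
    row <- complex(n)
    t0 <- 0L
    while (t0 < n) {
      idx <- ((t0 - hw):(t0 - hw + L - 1L)) %% n   # periodic extension
      y <- ifft(stats::fft(data[idx + 1L]) * Psi)
      nt <- min(B, n - t0)
      row[(t0 + 1L):(t0 + nt)] <- y[(hw + 1L):(hw + nt)]
      t0 <- t0 + B
    }
    row
  }, n_workers)
}

next_fast_len_v <- function(x) vapply(x, function(v)
  if (is.finite(v)) next_fast_len(v) else Inf, numeric(1))
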