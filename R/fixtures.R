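#' Synthetic test signals
#'
#' Seeded generators used throughout the test surface: multi-tone
#' mixtures in white noise, linear chirps, and a hippocampal-LFP-like
#' surrogate with a theta carrier, theta-nested (phase-amplitude
#' coupled) gamma, optional ripple bursts and 1/f background noise.
#' Every generator is bit-reproducible under its seed and stores the
#' ground-truth parameters needed to score detections.
#'
#' @name fixtures
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

synthetic_signal <- function(samples, fs, ground_truth, seed = NULL) {
  structure(list(samples = samples, fs = fs,
                 ground_truth = ground_truth, seed = seed),
            class = "synthetic_signal")
}

#' @export
print.synthetic_signal <- function(x, ...) {
  cat("synthetic_signal:", length(x$samples), "samples at", x$fs, "Hz (",
      x$ground_truth$kind, ")\n")
  invisible(x)
}

#' @rdname fixtures
#' @param freqs_hz Tone frequencies (each `< fs/2`).
#' @param amps Tone amplitudes (recycled to `length(freqs_hz)`).
#' @param fs Sampling rate in Hz.
#' @param dur_s Duration in seconds.
#' @param noise_sd Standard deviation of added white Gaussian noise.
#' @param seed RNG seed (bit-reproducibility).
#' @export
make_tones <- function(freqs_hz, amps = 1, fs, dur_s, noise_sd = 0,
                       seed = NULL) {
  if (length(freqs_hz) && any(freqs_hz >= fs / 2))
    stop("tone frequencies must be below Nyquist")
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  amps <- rep_len(amps, length(freqs_hz))
  x <- numeric(n)
  for (i in seq_along(freqs_hz))
    x <- x + amps[i] * cos(2 * pi * freqs_hz[i] * t)
  if (noise_sd > 0)
    x <- x + with_seed(seed, rnorm(n, sd = noise_sd))
  synthetic_signal(x, fs,
                   list(kind = "tones", freqs_hz = freqs_hz, amps = amps,
                        noise_sd = noise_sd), seed)
}

#' @rdname fixtures
#' @param f0,f1 Start and end instantaneous frequency in Hz (`< fs/2`).
#' @export
make_chirp <- function(f0, f1, fs, dur_s) {
  stopifnot(f0 < fs / 2, f1 < fs / 2, f0 > 0, f1 > 0)
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  # linear instantaneous frequency f(t) = f0 + (f1 - f0) t / T
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * dur_s))
  synthetic_signal(cos(phase), fs,
                   list(kind = "chirp", f0 = f0, f1 = f1, dur_s = dur_s,
                        phase_law = function(tt)
                          2 * pi * (f0 * tt + (f1 - f0) * tt^2 / (2 * dur_s)),
                        inst_freq = function(tt) f0 + (f1 - f0) * tt / dur_s),
                   NULL)
}

#' @rdname fixtures
#' @param theta_hz,gamma_hz,ripple_hz Carrier frequencies of the slow
#'   rhythm, the nested fast rhythm, and transient ripple bursts
#'   (`theta < gamma < ripple < fs/2`).
#' @param coupling_depth Phase-amplitude coupling depth d in `[0, 1]`:
#'   the gamma envelope is `(1 + d*cos(theta_phase)) / (1 + d)`.
#' @param ripple_times Burst center times in seconds (may be empty).
#' @param theta_amp,gamma_amp,ripple_amp Component amplitudes.
#' @param ripple_sd_s Gaussian half-duration of each burst in seconds.
#' @param noise_sd Standard deviation of the 1/f background noise.
#' @param noise_exponent Spectral exponent of the background
#'   (power ~ 1/f^exponent).
#' @export
make_lfp_surrogate <- function(fs, dur_s, theta_hz = 8, gamma_hz = 60,
                               coupling_depth = 0.5,
                               ripple_times = numeric(0), ripple_hz = 200,
                               theta_amp = 1, gamma_amp = 0.3,
                               ripple_amp = 1, ripple_sd_s = 0.02,
                               noise_sd = 0.2, noise_exponent = 1,
                               seed = NULL) {
  stopifnot(theta_hz < gamma_hz, gamma_hz < ripple_hz, ripple_hz < fs / 2,
            coupling_depth >= 0, coupling_depth <= 1)
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  theta_phase <- 2 * pi * theta_hz * t
  x <- theta_amp * cos(theta_phase)
  gamma_env <- (1 + coupling_depth * cos(theta_phase)) / (1 + coupling_depth)
  x <- x + gamma_amp * gamma_env * cos(2 * pi * gamma_hz * t)
  for (t0 in ripple_times) {
    win <- exp(-(t - t0)^2 / (2 * ripple_sd_s^2))
    x <- x + ripple_amp * win * cos(2 * pi * ripple_hz * (t - t0))
  }
  if (noise_sd > 0)
    x <- x + one_over_f_noise(n, fs, noise_sd, noise_exponent, seed)
  synthetic_signal(x, fs,
                   list(kind = "lfp_surrogate", theta_hz = theta_hz,
                        gamma_hz = gamma_hz, ripple_hz = ripple_hz,
                        coupling_depth = coupling_depth,
                        ripple_times = ripple_times,
                        gamma_envelope = gamma_env, noise_sd = noise_sd),
                   seed)
}

# 1/f^alpha background by spectral shaping of seeded white noise
# (amplitude ~ f^(-alpha/2)); rescaled to the requested sd
one_over_f_noise <- function(n, fs, sd, alpha, seed) {
  L <- next_fast_len(n)
  white <- with_seed(seed, rnorm(L))
  W <- stats::fft(white)
  f <- abs(grid_freqs(L)) * fs
  shape <- c(0, f[-1L]^(-alpha / 2))   # kill DC
  x <- Re(ifft(W * shape))[seq_len(n)]
  x * sd / stats::sd(x)
}
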