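# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, dense matrices) so they share no code
# path with the implementation they check.

# delay-corrected "same" convolution by direct summation:
# y[t] = sum_k h[k] x[t + delay - k], x zero outside its support (0-based)
oracle_convolve <- function(x, h, delay = (length(h) - 1) %/% 2, ds = 1) {
  n <- length(x)
  m <- length(h)
  xpad <- c(numeric(m), x, numeric(m))
  y <- vapply(0:(n - 1), function(t) {
    sum(h * xpad[t + delay - (0:(m - 1)) + m + 1])
  }, numeric(1))
  y[seq(1, n, by = ds)]
}

# double-loop DTFT
oracle_dtft <- function(taps, freqs_hz, fs) {
  vapply(freqs_hz, function(f) {
    acc <- 0 + 0i
    for (k in seq_along(taps))
      acc <- acc + taps[k] * exp(-2i * pi * f * (k - 1) / fs)
    acc
  }, complex(1))
}

# dense sinc concentration matrix for the DPSS eigenproblem
oracle_dpss_dense <- function(n, half_bandwidth_hz, fs, n_tapers) {
  w <- half_bandwidth_hz / fs
  ij <- outer(0:(n - 1), 0:(n - 1), "-")
  S <- sin(2 * pi * w * ij) / (pi * ij)
  diag(S) <- 2 * w
  ev <- eigen(S, symmetric = TRUE)
  list(vectors = ev$vectors[, seq_len(n_tapers), drop = FALSE],
       values = ev$values[seq_len(n_tapers)])
}

# maximum relative magnitude of negative-frequency content of a
# (supposedly analytic) sequence
neg_freq_content <- function(z) {
  S <- stats::fft(z)
  n <- length(z)
  neg <- S[(floor(n / 2) + 2):n]
  max(Mod(neg)) / max(Mod(S))
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))
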