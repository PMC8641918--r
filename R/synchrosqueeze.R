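#' Time derivative of the CWT
#'
#' Runs the same frequency-domain pipeline as [cwt()] with an additional
#' `j*omega` multiplier (omega in rad/s), giving the partial derivative
#' of the coefficients along time. Using one conjugation convention for
#' both transforms makes the ratio in the phase transform exact for
#' analytic tones (the frequency-domain wavelets are real-valued, so the
#' convention reduces to using the same `Psi` on both paths).
#'
#' @inheritParams cwt
#' @return A `tf_result` of complex derivatives, same shape as the CWT.
#' @export
cwt_time_derivative <- function(data, spec = morse_wavelet(), grid, fs,
                                method = c("full", "overlap_save"),
                                n_workers = 1L) {
  method <- match.arg(method)
  if (is.complex(data)) stop("real input required")
  data <- as.numeric(data)
  n <- length(data)
  stopifnot(inherits(grid, "scale_grid"))
  if (max(grid$freqs_hz) > fs / 2)
    stop("grid contains frequencies above Nyquist")
  hws <- vapply(grid$scales, function(a) wavelet_support(spec, a, fs),
                numeric(1))
  rows <- if (method == "full") {
    cwt_rows_full(data, spec, grid, hws, n_workers, fs, deriv = TRUE)
  } else {
    cwt_rows_ols(data, spec, grid, hws, n_workers, fs, deriv = TRUE)
  }
  tf_result(do.call(rbind, rows), grid$freqs_hz, (seq_len(n) - 1) / fs,
            method = "cwt_dt",
            meta = list(spec = spec, grid = grid, fs = fs,
                        cwt_method = method))
}

#' Phase transform: local instantaneous frequency of CWT points
#'
#' `omega_f = Im(dW / W) / (2*pi)` in Hz, evaluated where
#' `|W| > eps_rel * max|W|`; points below the threshold (where the ratio
#' is numerically meaningless) are returned as `NA` (unmapped). For an
#' analytic tone `exp(2i*pi*f*t)` the transform equals `f` exactly at
#' every valid point of every scale, which is what makes reassignment by
#' this quantity sharpen ridges without moving them.
#'
#' @param W_row,dW_row Equal-length complex vectors (or matrices) of CWT
#'   coefficients and their time derivatives.
#' @param eps_rel Relative magnitude threshold below which points are
#'   left unmapped.
#' @return Real vector/matrix of frequencies in Hz with `NA` at unmapped
#'   points.
#' @export
phase_transform <- function(W_row, dW_row, eps_rel = 1e-8) {
  stopifnot(length(W_row) == length(dW_row))
  mx <- max(abs(W_row))
  out <- Im(dW_row / W_row) / (2 * pi)
  out[abs(W_row) <= eps_rel * mx] <- NA_real_
  if (mx == 0) out[] <- NA_real_
  out
}

#' Wavelet synchrosqueezed transform
#'
#' Sharpens a CWT along the frequency axis: each coefficient `W(a, b)`
#' is assigned the instantaneous frequency given by the phase transform
#' and added into the frequency bin containing it — a simple additive
#' accumulation, performed independently at each time index, so time
#' resolution and uniform time sampling are preserved. Unmapped points
#' (below the magnitude threshold, or mapping outside the bin range) are
#' dropped. Coefficients are accumulated without scale weighting; the
#' result is a ridge-sharpened redistribution of CWT mass, not a
#' reconstruction operator.
#'
#' Default bins are the analysis grid's own log-spaced frequencies with
#' edges at geometric means of consecutive centers (half-open
#' `[lo, hi)`).
#'
#' @inheritParams cwt
#' @param bin_freqs Optional ascending bin-center frequencies in Hz.
#' @param eps_rel Phase-transform threshold relative to the global
#'   maximum `|W|`.
#' @return An `sst_result`: complex `coefs` (`n_bins x n_times`),
#'   `bin_freqs_hz`, `bin_edges_hz`, `times_s`, and metadata.
#' @export
wsst <- function(data, fs, spec = morse_wavelet(), grid,
                 bin_freqs = NULL, eps_rel = 1e-8,
                 method = c("full", "overlap_save"), n_workers = 1L) {
  method <- match.arg(method)
  W <- cwt(data, spec, grid, fs, method = method, n_workers = n_workers)
  dW <- cwt_time_derivative(data, spec, grid, fs, method = method,
                            n_workers = n_workers)
  if (is.null(bin_freqs)) bin_freqs <- grid$freqs_hz
  bin_freqs <- sort(as.numeric(bin_freqs))
  if (length(bin_freqs) < 1L) stop("empty bin set")
  edges <- bin_edges_geometric(bin_freqs)
  omega_f <- phase_transform(W$coefs, dW$coefs, eps_rel)
  n_bins <- length(bin_freqs)
  n_t <- ncol(W$coefs)
  acc <- matrix(complex(real = 0, imaginary = 0), n_bins, n_t)
  # half-open bins [edge_i, edge_{i+1}); findInterval with left.open=FALSE
  bin_of <- matrix(findInterval(omega_f, edges), nrow(W$coefs), n_t)
  bin_of[is.na(omega_f)] <- 0L
  bin_of[bin_of > n_bins] <- 0L
  bin_of[!is.na(omega_f) & omega_f >= edges[n_bins + 1L]] <- 0L
  for (s in seq_len(nrow(W$coefs))) {
    ok <- which(bin_of[s, ] > 0L)
    if (length(ok))
      acc[cbind(bin_of[s, ok], ok)] <- acc[cbind(bin_of[s, ok], ok)] +
        W$coefs[s, ok]
  }
  structure(list(coefs = acc, bin_freqs_hz = bin_freqs,
                 bin_edges_hz = edges, times_s = W$times_s,
                 meta = list(spec = spec, grid = grid, fs = fs,
                             eps_rel = eps_rel, cwt_method = method)),
            class = "sst_result")
}

# edges at geometric means of consecutive centers, extended one half
# ratio-step at both ends
bin_edges_geometric <- function(centers) {
  if (length(centers) == 1L) {
    r <- sqrt(2)
    return(c(centers / r, centers * r))
  }
  inner <- sqrt(centers[-length(centers)] * centers[-1L])
  r0 <- centers[2L] / centers[1L]
  rn <- centers[length(centers)] / centers[length(centers) - 1L]
  c(centers[1L] / sqrt(r0), inner, centers[length(centers)] * sqrt(rn))
}

#' @export
print.sst_result <- function(x, ...) {
  cat("sst_result:", nrow(x$coefs), "bins x", ncol(x$coefs), "times,",
      round(min(x$bin_freqs_hz), 3), "-", round(max(x$bin_freqs_hz), 3),
      "Hz\n")
  invisible(x)
}

#' Convert an SST result to a tf_result (e.g. for rendering)
#' @param x An `sst_result`.
#' @export
as_tf_result <- function(x) {
  stopifnot(inherits(x, "sst_result"))
  tf_result(x$coefs, x$bin_freqs_hz, x$times_s, method = "sst",
            meta = x$meta)
}
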