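#' Plan a blocked overlap-save convolution
#'
#' Overlap-save evaluates a long linear convolution as a sequence of
#' FFTs of fixed length `fft_len`: each block reuses the last
#' `n_kernel - 1` input samples of its predecessor and contributes
#' `block_len = fft_len - n_kernel + 1` new output samples. When
#' `fft_len` is not given, the smallest 5-smooth length at least
#' `4 * n_kernel` is chosen (a standard efficiency point for
#' overlap-save), capped at the 5-smooth length covering the whole
#' convolution when the signal is short.
#'
#' @param n_signal Number of input samples per channel.
#' @param n_kernel Kernel (tap) count, `>= 1`.
#' @param ds Integer downsampling factor applied to the output.
#' @param fft_len Optional FFT length override (`>= n_kernel`; rounded up
#'   to 5-smooth).
#' @param delay Samples discarded at the front for group-delay
#'   correction.
#' @param dtype_out Output element type label.
#' @return A `conv_plan` with `fft_len`, `block_len`, `n_out`, etc.
#' @export
plan_overlap_save <- function(n_signal, n_kernel, ds = 1, fft_len = NULL,
                              delay = 0, dtype_out = "float64") {
  stopifnot(n_kernel >= 1, ds >= 1, n_signal >= 1)
  full_len <- next_fast_len(n_signal + n_kernel - 1)
  if (is.null(fft_len)) {
    fft_len <- min(next_fast_len(4 * n_kernel), full_len)
  } else {
    if (fft_len < n_kernel) stop("fft_len must be at least n_kernel")
    fft_len <- next_fast_len(fft_len)
  }
  structure(list(n_signal = n_signal, n_kernel = n_kernel,
                 fft_len = fft_len, block_len = fft_len - n_kernel + 1,
                 ds = as.integer(ds), delay = delay,
                 n_out = ceiling(n_signal / ds), dtype_out = dtype_out),
            class = "conv_plan")
}

#' FIR-filter data with fused delay correction and downsampling
#'
#' Filters each channel by blocked overlap-save FFT convolution and, in
#' the same pass, corrects for the filter's group delay and keeps only
#' every `ds`-th sample, so no full-rate intermediate is ever
#' materialized. With `correct_delay`, the output is the "same"-length
#' convolution advanced by `K = (M-1)/2` samples (`y[t] = sum_k h[k] *
#' x[t + K - k]`, input zero-extended at both ends), then decimated at
#' indices `0, ds, 2*ds, ...`; edge samples within K of either boundary
#' are contaminated by the zero extension. Delay correction requires an
#' odd tap count (integer delay).
#'
#' @param data Numeric vector, `channels x samples` matrix, or an
#'   [array_store][as_array_store].
#' @param taps FIR taps (numeric vector or `fir_filter`).
#' @param ds Integer downsampling factor.
#' @param correct_delay Advance the output by the group delay.
#' @param out Optional preallocated output store of the dry-run shape.
#' @param describe If `TRUE`, perform no computation and return the
#'   [dry_run()] sizing information.
#' @param fft_len,chunk_hint Optional tuning knobs: FFT length and
#'   samples per chunked read of on-disk input.
#' @param n_workers Channels are independent work items; how many to
#'   process concurrently. The result is identical for any value.
#' @return Filtered (and downsampled) vector/matrix; when `out` is given
#'   it is filled and returned invisibly; a `dry_run_info` when
#'   `describe = TRUE`.
#' @export
filter_data_fir <- function(data, taps, ds = 1, correct_delay = TRUE,
                            out = NULL, describe = FALSE, fft_len = NULL,
                            chunk_hint = NULL, n_workers = 1L) {
  if (inherits(taps, "fir_filter")) taps <- taps$taps
  taps <- as.numeric(taps)
  m <- length(taps)
  if (correct_delay && m %% 2L == 0L)
    stop("delay correction needs an odd tap count (integer group delay)")
  was_vector <- !is.matrix(data) && !inherits(data, "array_store")
  store_in <- as_array_store(data)
  d <- dim(store_in)
  n_ch <- d[1L]
  n <- d[2L]
  delay <- if (correct_delay) (m - 1L) %/% 2L else 0L
  plan <- plan_overlap_save(n, m, ds = ds, fft_len = fft_len, delay = delay)
  info <- dry_run_info(c(n_ch, plan$n_out), plan$dtype_out,
                       n_ch * ceiling(n / plan$block_len))
  if (describe) return(info)
  user_out <- !is.null(out)
  if (is.null(out)) {
    out <- mem_store_create(info$out_shape, info$out_dtype)
  } else {
    if (!all(dim(out) == info$out_shape))
      stop("out has shape (", paste(dim(out), collapse = ", "),
           "); dry run requires (", paste(info$out_shape, collapse = ", "), ")")
  }
  H <- stats::fft(c(taps, numeric(plan$fft_len - m)))
  if (is.null(chunk_hint))
    chunk_hint <- plan$block_len * max(1, ceiling(2^22 / plan$block_len))
  # channels are independent work items; forked workers are only used
  # when the output is disk-backed (writes then persist across processes)
  workers <- if (store_backing(out) == "disk") n_workers else 1L
  invisible(map_workers(seq_len(n_ch), function(ch) {
    ols_filter_channel(store_in, ch, n, H, m, plan, delay, chunk_hint, out)
  }, workers))
  if (!user_out)
    return(vec_or_matrix(as.matrix(out), was_vector))
  invisible(out)
}

# One channel of fused overlap-save filtering. Blocks are grouped into
# chunks of ~chunk_hint samples so on-disk inputs are read in large
# contiguous slices; the per-block math is identical regardless of
# chunking, so output does not depend on chunk_hint.
ols_filter_channel <- function(store_in, ch, n, H, m, plan, delay,
                               chunk_hint, out) {
  B <- plan$block_len
  L <- plan$fft_len
  ds <- plan$ds
  blocks_per_chunk <- max(1L, floor(chunk_hint / B))
  n_blocks <- ceiling(n / B)
  read_padded <- function(from, to) {
    # 0-based [from, to) with zero extension outside [0, n)
    lo <- max(from, 0L)
    hi <- min(to, n)
    seg <- numeric(to - from)
    if (hi > lo)
      seg[(lo - from + 1L):(hi - from)] <- store_read(store_in, ch, lo + 1L, hi)
    seg
  }
  b0 <- 0L
  while (b0 < n_blocks) {
    b1 <- min(b0 + blocks_per_chunk, n_blocks)
    # chunk covers delay-corrected output samples [s0, b1*B); the read is
    # zero-extended so every block sees its full fft_len input window
    s0 <- b0 * B
    chunk_in <- read_padded(s0 + delay - (m - 1L), b1 * B + delay)
    for (b in seq.int(b0, b1 - 1L)) {
      t0 <- b * B
      t1 <- min(t0 + B, n)
      off <- t0 - s0              # offset of this block in the chunk
      seg <- chunk_in[(off + 1L):(off + L)]
      y <- Re(ifft(stats::fft(seg) * H))[m:L]   # valid causal samples
      keep_t <- seq.int(t0, t1 - 1L)
      sel <- which(keep_t %% ds == 0L)
      if (length(sel))
        store_write(out, ch, keep_t[sel[1L]] %/% ds + 1L, y[sel])
    }
    b0 <- b1
  }
  invisible(NULL)
}
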