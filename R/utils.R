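#' @useDynLib blockspec, .registration = TRUE
#' @importFrom stats fft rnorm median coef lm
#' @importFrom utils head tail
NULL

#' Smallest 5-smooth integer not below `n`
#'
#' FFTs of lengths whose prime factors are at most 5 are computed
#' efficiently by the mixed-radix backend; all internal transform lengths
#' are rounded up to such a length.
#'
#' @param n Positive integer.
#' @return The smallest integer `>= n` with no prime factor larger than 5.
#' @examples
#' next_fast_len(404)  # 405 = 3^4 * 5
#' @export
next_fast_len <- function(n) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 1)
  n <- as.numeric(ceiling(n))
  if (n <= 6) return(n)
  m <- n
  repeat {
    if (is_5smooth(m)) return(m)
    m <- m + 1
  }
}

is_5smooth <- function(m) {
  while (m %% 2 == 0) m <- m / 2
  while (m %% 3 == 0) m <- m / 3
  while (m %% 5 == 0) m <- m / 5
  m == 1
}

# unnormalized inverse FFT wrapper; keep the 1/L in one place
ifft <- function(z) stats::fft(z, inverse = TRUE) / length(z)

# map over work items, optionally forking; results always returned in
# input order so the output is independent of the worker count
map_workers <- function(xs, fn, n_workers = 1L) {
  n_workers <- max(1L, as.integer(n_workers))
  if (n_workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(xs, fn, mc.cores = n_workers)
  } else {
    lapply(xs, fn)
  }
}

# 1-D input is treated as one channel; remember to drop on the way out
as_channel_matrix <- function(data) {
  if (is.matrix(data)) data else matrix(data, nrow = 1L)
}

vec_or_matrix <- function(m, was_vector) {
  if (was_vector) drop(m[1L, , drop = TRUE]) else m
}
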