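#' Array stores: a chunk-addressable array contract
#'
#' Long recordings and their time-frequency decompositions frequently do
#' not fit in memory. Every bulk operation in this package therefore reads
#' from and writes to an *array store*: any object exposing a shape, an
#' element type, and slice read/write along the sample axis. Two backings
#' are provided: an in-memory matrix and a flat binary file with a JSON
#' sidecar (layout `(n_channels, n_samples)`, each channel contiguous on
#' disk so sample-range I/O is a single seek).
#'
#' @param x A numeric/complex vector or matrix (`channels x samples`).
#' @return An object of class `array_store`.
#' @export
as_array_store <- function(x) {
  if (inherits(x, "array_store")) return(x)
  stopifnot(is.numeric(x) || is.complex(x))
  env <- new.env(parent = emptyenv())
  env$data <- as_channel_matrix(x)
  structure(list(env = env,
                 dtype = if (is.complex(x)) "complex128" else "float64"),
            class = c("mem_store", "array_store"))
}

#' Create an empty in-memory store
#' @param shape `c(n_channels, n_samples)`.
#' @param dtype One of `"float64"`, `"float32"`, `"complex128"`,
#'   `"complex64"`, `"int16"`, `"int32"`.
#' @export
mem_store_create <- function(shape, dtype = "float64") {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 0L))
  fill <- if (grepl("^complex", dtype)) complex(real = 0, imaginary = 0) else 0
  env <- new.env(parent = emptyenv())
  env$data <- matrix(fill, nrow = shape[1L], ncol = shape[2L])
  structure(list(env = env, dtype = dtype),
            class = c("mem_store", "array_store"))
}

#' Create a preallocated on-disk store
#'
#' Writes a zero-filled flat binary file of the full output size plus a
#' `<path>.json` sidecar recording shape, dtype and chunk hint, mirroring
#' the dry-run/preallocate call pattern used for out-of-core outputs.
#'
#' @param path File path for the binary payload.
#' @inheritParams mem_store_create
#' @param chunk_hint Advisory samples-per-access used by chunked readers.
#' @export
disk_store_create <- function(path, shape, dtype = "float64",
                              chunk_hint = 2^22) {
  shape <- as.numeric(shape)
  stopifnot(length(shape) == 2L, all(shape >= 0), dtype %in% names(.itemsize))
  meta <- list(shape = shape, dtype = dtype, chunk_hint = chunk_hint)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  nbytes <- prod(shape) * .itemsize[[dtype]]
  con <- file(path, "wb")
  on.exit(close(con))
  # zero-fill in bounded pieces so creation itself is out-of-core safe
  left <- nbytes
  zeros <- raw(2^20)
  while (left > 0) {
    take <- min(left, length(zeros))
    writeBin(zeros[seq_len(take)], con)
    left <- left - take
  }
  disk_store_open(path)
}

#' Open an existing on-disk store
#' @param path Path passed to [disk_store_create()].
#' @export
disk_store_open <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(path = path, shape = as.numeric(meta$shape),
                 dtype = meta$dtype, chunk_hint = meta$chunk_hint),
            class = c("disk_store", "array_store"))
}

.itemsize <- c(float64 = 8, float32 = 4, complex128 = 16, complex64 = 8,
               int16 = 2, int32 = 4)

#' @export
dim.mem_store <- function(x) dim(x$env$data)
#' @export
dim.disk_store <- function(x) as.integer(x$shape)

#' Element type of a store
#' @param store An `array_store`.
#' @export
store_dtype <- function(store) store$dtype

#' Backing medium of a store
#' @param store An `array_store`.
#' @return `"memory"` or `"disk"`.
#' @export
store_backing <- function(store) {
  if (inherits(store, "disk_store")) "disk" else "memory"
}

#' Read a sample slice of one channel
#' @param store An `array_store`.
#' @param channel 1-based channel index.
#' @param from,to 1-based inclusive sample range.
#' @return Numeric or complex vector of length `to - from + 1`.
#' @export
store_read <- function(store, channel, from, to) UseMethod("store_read")

#' Write a sample slice of one channel
#' @inheritParams store_read
#' @param values Vector to write starting at `from`.
#' @export
store_write <- function(store, channel, from, values) UseMethod("store_write")

#' @export
store_read.mem_store <- function(store, channel, from, to) {
  store$env$data[channel, from:to]
}

#' @export
store_write.mem_store <- function(store, channel, from, values) {
  store$env$data[channel, from + seq_along(values) - 1L] <- values
  invisible(store)
}

disk_offset_bytes <- function(store, channel, from) {
  ((channel - 1) * store$shape[2L] + (from - 1)) * .itemsize[[store$dtype]]
}

#' @export
store_read.disk_store <- function(store, channel, from, to) {
  n <- to - from + 1
  con <- file(store$path, "rb")
  on.exit(close(con))
  seek(con, disk_offset_bytes(store, channel, from))
  switch(store$dtype,
    float64    = readBin(con, "double", n),
    float32    = readBin(con, "double", n, size = 4),
    complex128 = readBin(con, "complex", n),
    complex64  = {
      parts <- readBin(con, "double", 2 * n, size = 4)
      complex(real = parts[c(TRUE, FALSE)], imaginary = parts[c(FALSE, TRUE)])
    },
    int16      = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE)),
    int32      = as.numeric(readBin(con, "integer", n)),
    stop("unsupported dtype: ", store$dtype))
}

#' @export
store_write.disk_store <- function(store, channel, from, values) {
  con <- file(store$path, "r+b")
  on.exit(close(con))
  seek(con, disk_offset_bytes(store, channel, from), rw = "write")
  switch(store$dtype,
    float64    = writeBin(as.double(values), con),
    float32    = writeBin(as.double(values), con, size = 4),
    complex128 = writeBin(as.complex(values), con),
    complex64  = {
      v <- as.complex(values)
      writeBin(as.double(rbind(Re(v), Im(v))), con, size = 4)
    },
    int16      = writeBin(as.integer(values), con, size = 2),
    int32      = writeBin(as.integer(values), con),
    stop("unsupported dtype: ", store$dtype))
  invisible(store)
}

#' Materialize a store as a matrix
#' @param x An `array_store`.
#' @param ... Unused.
#' @export
as.matrix.mem_store <- function(x, ...) x$env$data

#' @export
as.matrix.disk_store <- function(x, ...) {
  d <- dim(x)
  out <- matrix(if (grepl("^complex", x$dtype)) complex(1) else 0,
                d[1L], d[2L])
  for (ch in seq_len(d[1L]))
    out[ch, ] <- store_read(x, ch, 1L, d[2L])
  out
}

#' Dry-run sizing for bulk operations
#'
#' Computes the exact output geometry of a supported operation without
#' touching bulk data, so the caller can preallocate an on-disk output of
#' the right shape before running the real computation.
#'
#' @param op A named list describing the operation. `op$op` must be
#'   `"filter_data_fir"` (fields: `n_channels`, `n_samples`, `n_taps`,
#'   `ds`, optionally `dtype_out`, `fft_len`) or `"cwt"` (fields:
#'   `n_samples` and `n_freqs` or `grid`, optionally `dtype_out`).
#' @return A `dry_run_info` with `out_shape`, `out_dtype`,
#'   `bytes_required`, and `n_chunks` (planned independent work items).
#' @export
dry_run <- function(op) {
  stopifnot(is.list(op), !is.null(op$op))
  switch(op$op,
    filter_data_fir = {
      ds <- if (is.null(op$ds)) 1 else op$ds
      dtype <- if (is.null(op$dtype_out)) "float64" else op$dtype_out
      plan <- plan_overlap_save(op$n_samples, op$n_taps, ds = ds,
                                fft_len = op$fft_len)
      n_blocks <- ceiling(op$n_samples / plan$block_len)
      dry_run_info(c(op$n_channels, plan$n_out), dtype,
                   op$n_channels * n_blocks)
    },
    cwt = {
      n_freqs <- if (!is.null(op$grid)) length(op$grid$freqs_hz) else op$n_freqs
      dtype <- if (is.null(op$dtype_out)) "complex128" else op$dtype_out
      dry_run_info(c(n_freqs, op$n_samples), dtype, n_freqs)
    },
    stop("unsupported op: ", op$op))
}

dry_run_info <- function(out_shape, out_dtype, n_chunks) {
  structure(list(out_shape = as.numeric(out_shape), out_dtype = out_dtype,
                 bytes_required = prod(out_shape) * .itemsize[[out_dtype]],
                 n_chunks = n_chunks),
            class = "dry_run_info")
}

#' @export
print.dry_run_info <- function(x, ...) {
  cat("dry run: shape (", paste(x$out_shape, collapse = ", "), ") ",
      x$out_dtype, ", ", format_bytes_binary(x$bytes_required)$pretty,
      ", ", x$n_chunks, " work items\n", sep = "")
  invisible(x)
}

#' Storage requirement of a recording
#'
#' Simple arithmetic used when sizing outputs and deciding whether a
#' computation must run out-of-core: `n_channels * n_samples * itemsize`
#' bytes, reported with binary prefixes (MiB = 2^20 bytes, GiB = 2^30).
#'
#' @param n_channels,n_samples Nonnegative integers.
#' @param itemsize Bytes per sample (2 for int16, 8 for float64, ...).
#' @return A list with `bytes`, `mib`, `gib` and a `pretty` string (whole
#'   GiB, rounded down, when at least 1 GiB; otherwise MiB to one decimal).
#' @examples
#' storage_estimate(256, 3600 * 30000, 2)  # 51 GiB
#' @export
storage_estimate <- function(n_channels, n_samples, itemsize) {
  stopifnot(n_channels >= 0, n_samples >= 0, itemsize > 0)
  format_bytes_binary(n_channels * n_samples * itemsize)
}

format_bytes_binary <- function(bytes) {
  mib <- bytes / 2^20
  gib <- bytes / 2^30
  pretty <- if (gib >= 1) sprintf("%d GiB", floor(gib))
            else sprintf("%.1f MiB", round(mib, 1))
  structure(list(bytes = bytes, mib = mib, gib = gib, pretty = pretty),
            class = "storage_estimate")
}

#' @export
print.storage_estimate <- function(x, ...) {
  cat(format(x$bytes, big.mark = ","), "bytes =", x$pretty, "\n")
  invisible(x)
}
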