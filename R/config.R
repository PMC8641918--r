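#' Run configuration
#'
#' Resource knobs shared by the bulk entry points: how many parallel
#' work items to process, FFT threading (carried for configuration
#' compatibility; the FFT backend used here is single-threaded), the
#' advisory chunk size for on-disk reads, logging verbosity, and a seed
#' for any randomized step. Round-trips through YAML.
#'
#' @param worker_count,fft_threads Positive integers.
#' @param chunk_hint Samples per chunked read (positive).
#' @param log_level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param seed Optional integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(worker_count = 1L, fft_threads = 1L,
                       chunk_hint = 2^22, log_level = "info", seed = NULL) {
  stopifnot(worker_count >= 1, fft_threads >= 1, chunk_hint >= 1,
            log_level %in% c("debug", "info", "warn", "error"))
  structure(list(worker_count = as.integer(worker_count),
                 fft_threads = as.integer(fft_threads),
                 chunk_hint = as.numeric(chunk_hint),
                 log_level = log_level,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
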